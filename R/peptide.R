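#' @name peptide
#' @title Peptide sequences and the charge quantities of the electrodiffusion
#'   analysis
#'
#' @description
#' The reversal-potential analysis treats the translocating peptide as a point
#' charge whose effective valence is set by its ionisable side chains, and the
#' accompanying counterions by simple charge balance. Protamine (salmine), a
#' 32-residue arginine-rich polycation, carries one elementary charge per
#' arginine and no acidic residues, so its effective charge equals its
#' arginine count (+21 e) and 11 divalent sulfate counterions neutralise it.
#' These functions parse sequences from FASTA and compute those quantities.
NULL

.AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residue (i.e. water-free) masses, Da
.AA_MASS_AVERAGE <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
.WATER_AVERAGE <- 18.01528
.WATER_MONO <- 18.010565

#' Construct a peptide record
#'
#' @param name sequence name.
#' @param sequence amino-acid string over the 20 one-letter codes
#'   (case-insensitive; stored upper-case).
#' @return an object of class `peptide_record` with elements `name` and
#'   `sequence`.
#' @examples
#' peptide_record("tetra-arg", "RRRR")
#' @export
peptide_record <- function(name, sequence) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(seq) == 0L) {
    stop("empty sequence", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% .AA_CODES))
  if (length(bad)) {
    stop(sprintf("illegal residue character '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], name), call. = FALSE)
  }
  structure(list(name = as.character(name), sequence = seq),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record> %s (%d aa)\n%s\n",
              x$name, nchar(x$sequence), x$sequence))
  invisible(x)
}

#' Read peptide records from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that validates every
#' residue against the 20 standard one-letter codes and upper-cases the
#' stored sequences.
#'
#' @param path path to a FASTA file.
#' @return a list of [peptide_record()] objects in file order.
#' @examples
#' fa <- system.file("extdata", "protamine.fasta", package = "porekin")
#' ptm <- read_fasta(fa)[[1]]
#' nchar(ptm$sequence) # 32
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  nm <- names(set)
  if (is.null(nm)) nm <- rep("", length(set))
  # keep only the identifier token of each header line
  nm <- sub("[[:space:]].*$", "", nm)
  lapply(seq_along(set), function(i) {
    peptide_record(nm[i], as.character(set[[i]]))
  })
}

#' Side-chain charge model
#'
#' Defines which residues count as charged and the valence of the mobile
#' counterion used for stoichiometry. The default counts only Arg/Lys (+1)
#' and Asp/Glu (-1) side chains and ignores the termini and histidine: for
#' protamine this reproduces the effective charge assumed by the
#' reversal-potential analysis (+21 e, equal to the arginine count). The
#' default counterion is sulfate (-2 e), the salt form of the peptide.
#'
#' @param basic_residues one-letter codes contributing +1 each.
#' @param acidic_residues one-letter codes contributing -1 each.
#' @param include_termini if `TRUE`, add +1 for the N-terminus and -1 for the
#'   C-terminus (net 0 for a free peptide).
#' @param counterion_valence signed counterion valence in e units (nonzero).
#' @return an object of class `charge_model`.
#' @export
charge_model <- function(basic_residues = c("R", "K"),
                         acidic_residues = c("D", "E"),
                         include_termini = FALSE,
                         counterion_valence = -2L) {
  basic <- toupper(basic_residues)
  acidic <- toupper(acidic_residues)
  if (length(intersect(basic, acidic))) {
    stop("basic and acidic residue sets must be disjoint", call. = FALSE)
  }
  if (!all(c(basic, acidic) %in% .AA_CODES)) {
    stop("charged residue sets must use the 20 one-letter codes",
         call. = FALSE)
  }
  .check_number(counterion_valence, "counterion_valence", allow_zero = FALSE)
  structure(list(basic_residues = basic, acidic_residues = acidic,
                 include_termini = isTRUE(include_termini),
                 counterion_valence = as.integer(counterion_valence)),
            class = "charge_model")
}

#' Net charge of a peptide under a side-chain charge model
#'
#' @param peptide a [peptide_record()].
#' @param model a [charge_model()].
#' @return signed integer net charge in e units.
#' @examples
#' net_charge(peptide_record("x", "RKDE"), charge_model()) # 0
#' @export
net_charge <- function(peptide, model = charge_model()) {
  stopifnot(inherits(peptide, "peptide_record"), inherits(model, "charge_model"))
  chars <- strsplit(peptide$sequence, "")[[1]]
  q <- sum(chars %in% model$basic_residues) - sum(chars %in% model$acidic_residues)
  # free termini carry +1 (N) and -1 (C): net zero, kept explicit
  if (model$include_termini) q <- q + 1L - 1L
  as.integer(q)
}

#' Count occurrences of a residue in a peptide
#'
#' @param peptide a [peptide_record()].
#' @param residue a single one-letter amino-acid code.
#' @return nonnegative integer count.
#' @export
residue_count <- function(peptide, residue) {
  stopifnot(inherits(peptide, "peptide_record"))
  res <- toupper(residue)
  if (length(res) != 1L || !(res %in% .AA_CODES)) {
    stop(sprintf("invalid residue code '%s'", residue), call. = FALSE)
  }
  sum(strsplit(peptide$sequence, "")[[1]] == res)
}

#' Counterion stoichiometry by charge balance
#'
#' The smallest integer number of counterions whose total charge magnitude is
#' at least the peptide's: `ceiling(|q| / |z_counter|)`. For protamine
#' (+21 e) with sulfate (-2 e) this gives the 11 mobile sulfate ions assumed
#' by the reversal-potential analysis.
#'
#' @param peptide_charge signed peptide net charge, e units.
#' @param counterion_valence signed counterion valence, e units (nonzero,
#'   opposite sign to `peptide_charge`).
#' @return nonnegative integer number of counterions.
#' @examples
#' counterion_stoichiometry(21, -2) # 11
#' @export
counterion_stoichiometry <- function(peptide_charge, counterion_valence) {
  .check_number(peptide_charge, "peptide_charge")
  .check_number(counterion_valence, "counterion_valence", allow_zero = FALSE)
  if (peptide_charge == 0) return(0L)
  if (sign(peptide_charge) == sign(counterion_valence)) {
    stop("counterion valence must be opposite in sign to the peptide charge",
         call. = FALSE)
  }
  as.integer(ceiling(abs(peptide_charge) / abs(counterion_valence)))
}

#' Molecular mass of the free-base peptide
#'
#' Sum of residue masses plus one water. Provided as a convenience; note that
#' vendor-quoted masses of polycation salts (e.g. protamine sulfate) include
#' the counterions and exceed the free-base mass computed here.
#'
#' @param peptide a [peptide_record()].
#' @param type `"average"` or `"monoisotopic"` residue-mass table.
#' @return mass in Da.
#' @export
peptide_mass <- function(peptide, type = c("average", "monoisotopic")) {
  stopifnot(inherits(peptide, "peptide_record"))
  type <- match.arg(type)
  tab <- if (type == "average") .AA_MASS_AVERAGE else .AA_MASS_MONO
  water <- if (type == "average") .WATER_AVERAGE else .WATER_MONO
  chars <- strsplit(peptide$sequence, "")[[1]]
  sum(tab[chars]) + water
}

#' Charge report for a peptide
#'
#' One-stop summary used by the worked example: length, arginine count, net
#' charge and counterion stoichiometry.
#'
#' @inheritParams net_charge
#' @return a list with elements `name`, `length`, `arg_count`,
#'   `net_charge_e`, `counterion_count`.
#' @export
peptide_report <- function(peptide, model = charge_model()) {
  q <- net_charge(peptide, model)
  list(name = peptide$name,
       length = nchar(peptide$sequence),
       arg_count = residue_count(peptide, "R"),
       net_charge_e = q,
       counterion_count = counterion_stoichiometry(q, model$counterion_valence))
}
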