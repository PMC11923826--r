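# Amino-acid property tables and the numeric primitives applied to
# sequence windows and peptides. Every table covers exactly the 20
# standard residues; nonstandard letters (U, X, B, Z, ...) are never
# assigned a fabricated value -- functions return NA with a flag instead.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, in the conventional order.
#' @export
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Kyte-Doolittle hydropathy (positive = hydrophobic)
.KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Zimmerman-Eliezer-Simha polarity
.POLARITY <- c(
  A =  0.00, R = 52.00, N =  3.38, D = 49.70, C =  1.48,
  Q =  3.53, E = 49.90, G =  0.00, H = 51.60, I =  0.13,
  L =  0.13, K = 49.50, M =  1.43, F =  0.35, P =  1.58,
  S =  1.67, T =  1.66, W =  2.10, Y =  1.61, V =  0.13
)

# Zhao-London transmembrane tendency
.TM_TENDENCY <- c(
  A =  0.38, R = -2.57, N = -1.62, D = -3.27, C = -0.30,
  Q = -1.84, E = -2.90, G = -0.19, H = -1.44, I =  1.97,
  L =  1.82, K = -3.46, M =  1.40, F =  1.98, P = -1.44,
  S = -0.53, T = -0.32, W =  1.53, Y =  0.49, V =  1.46
)

# Average (not monoisotopic) residue masses, Da
.MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)

# Formal side-chain charge at physiological pH; His carries 0 by convention
.CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

#' Mass of one water molecule (average), Da
#' @export
WATER_MASS <- 18.01528

.SCALE_REGISTRY <- list(
  kd_hydropathy = .KD_HYDROPATHY,
  polarity      = .POLARITY,
  tm_tendency   = .TM_TENDENCY,
  mass_avg      = .MASS_AVG,
  charge        = .CHARGE
)

#' Retrieve a built-in amino-acid property table
#'
#' @param name One of `"kd_hydropathy"` (Kyte-Doolittle hydropathy),
#'   `"polarity"` (Zimmerman), `"tm_tendency"` (Zhao-London
#'   transmembrane tendency), `"mass_avg"` (average residue mass, Da) or
#'   `"charge"` (formal side-chain charge).
#' @return A named numeric vector over the 20 standard residues.
#' @export
aa_scale <- function(name = c("kd_hydropathy", "polarity", "tm_tendency",
                              "mass_avg", "charge")) {
  name <- match.arg(name)
  .SCALE_REGISTRY[[name]]
}

#' Read a residue property table from a two-column delimited file
#'
#' Users can substitute any of the built-in tables with their own
#' (residue, value) file; the packaged defaults live under
#' `system.file("extdata", "scales", package = "topopalm")`.
#'
#' @param path Path to a tab-separated file with columns `residue`, `value`.
#' @return Named numeric vector; errors unless all 20 standard residues
#'   are present exactly once.
#' @export
read_scale_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab))) {
    stop("scale table must have columns 'residue' and 'value': ", path)
  }
  v <- stats::setNames(as.numeric(tab$value), tab$residue)
  if (!setequal(names(v), AA_STANDARD) || anyDuplicated(names(v))) {
    stop("scale table must cover exactly the 20 standard residues once each: ",
         path)
  }
  v[AA_STANDARD]
}

.split_residues <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

.has_nonstandard <- function(residues) {
  any(!residues %in% AA_STANDARD)
}

#' Mean of a residue property over a sequence
#'
#' @param seq Nonempty residue string.
#' @param scale Named numeric vector over the standard residues (see
#'   [aa_scale()]).
#' @return Arithmetic mean of per-residue values. If `seq` contains a
#'   nonstandard residue the result is `NA` with attribute
#'   `nonstandard = TRUE` (no value is ever fabricated).
#' @export
mean_scale <- function(seq, scale) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("mean_scale() requires a nonempty residue string")
  }
  res <- .split_residues(seq)
  if (.has_nonstandard(res)) {
    return(structure(NA_real_, nonstandard = TRUE))
  }
  mean(scale[res])
}

#' Average peptide mass in daltons
#'
#' Sum of average residue masses plus one water (18.01528 Da). Average
#' rather than monoisotopic masses are used because downstream
#' detectability windows are coarse heuristics, for which average masses
#' are the conventional choice.
#'
#' @param seq Nonempty residue string of standard residues.
#' @return Mass in Da.
#' @export
peptide_mass <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("peptide_mass() requires a nonempty residue string")
  }
  res <- .split_residues(seq)
  if (.has_nonstandard(res)) {
    stop("peptide_mass(): nonstandard residue in '", seq, "'")
  }
  sum(.MASS_AVG[res]) + WATER_MASS
}

#' Net formal charge of a sequence
#'
#' +1 per Lys/Arg, -1 per Asp/Glu; His counts 0 (physiological-pH
#' convention). The empty string has charge 0.
#'
#' @param seq Residue string (may be empty).
#' @return Integer-valued net charge; `NA` (flagged) on nonstandard
#'   residues.
#' @export
net_charge <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("net_charge() requires a single string")
  }
  if (!nzchar(seq)) return(0)
  res <- .split_residues(seq)
  if (.has_nonstandard(res)) {
    return(structure(NA_real_, nonstandard = TRUE))
  }
  sum(.CHARGE[res])
}

#' Aliphatic index (Ikai)
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` where `X` is the mole
#' percentage of each residue in the sequence.
#'
#' @param seq Nonempty residue string.
#' @return Aliphatic index; `NA` (flagged) on nonstandard residues.
#' @export
aliphatic_index <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("aliphatic_index() requires a nonempty residue string")
  }
  res <- .split_residues(seq)
  if (.has_nonstandard(res)) {
    return(structure(NA_real_, nonstandard = TRUE))
  }
  n <- length(res)
  molpct <- function(aa) 100 * sum(res == aa) / n
  molpct("A") + 2.9 * molpct("V") + 3.9 * (molpct("I") + molpct("L"))
}

#' Mean transmembrane tendency (Zhao-London scale)
#' @inheritParams mean_scale
#' @export
tm_tendency_mean <- function(seq) mean_scale(seq, .TM_TENDENCY)

#' Mean polarity (Zimmerman scale)
#' @inheritParams mean_scale
#' @export
polarity_mean <- function(seq) mean_scale(seq, .POLARITY)

#' Mean Kyte-Doolittle hydropathy
#' @inheritParams mean_scale
#' @export
kd_mean <- function(seq) mean_scale(seq, .KD_HYDROPATHY)
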