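# Synthetic topology-annotated proteomes with planted juxtamembrane
# palmitoylation labels. The generator emulates the statistical
# structure the features assume -- alternating topology, hydrophobic
# transmembrane cores, charged/polar loops, cysteine clustering near
# interfaces -- so the whole pipeline is trainable and testable with
# no external download. The planted rule uses ONLY the interface
# distance, so feature-importance recovery has an unambiguous
# expected answer.

.norm_comp <- function(x) x / sum(x)

# Per-kind residue composition over the 19 non-Cys standard residues;
# cysteines are mixed in separately at the per-kind cys_rate.
.COMPOSITION <- list(
  Transmembrane = .norm_comp(c(
    A = 0.12, R = 0.00, N = 0.01, D = 0.00, Q = 0.01, E = 0.00,
    G = 0.07, H = 0.01, I = 0.14, L = 0.19, K = 0.00, M = 0.05,
    F = 0.10, P = 0.02, S = 0.05, T = 0.05, W = 0.03, Y = 0.03,
    V = 0.12)),
  Loop = .norm_comp(c(
    A = 0.08, R = 0.06, N = 0.04, D = 0.06, Q = 0.04, E = 0.08,
    G = 0.07, H = 0.02, I = 0.04, L = 0.08, K = 0.07, M = 0.02,
    F = 0.03, P = 0.05, S = 0.08, T = 0.06, W = 0.01, Y = 0.03,
    V = 0.05)),
  Signal = .norm_comp(c(
    A = 0.14, R = 0.02, N = 0.01, D = 0.01, Q = 0.02, E = 0.01,
    G = 0.08, H = 0.01, I = 0.08, L = 0.24, K = 0.02, M = 0.04,
    F = 0.08, P = 0.04, S = 0.07, T = 0.05, W = 0.03, Y = 0.02,
    V = 0.10))
)

#' Parameters of the synthetic proteome generator
#'
#' Defaults define the reference simulation conditions used throughout
#' the test-suite: 500 proteins of 1-4 transmembrane segments with a
#' planted label rule in which a cysteine within `d_near = 10`
#' residues of the membrane interface is palmitoylated with
#' probability `p_near = 0.8` and any other eligible cysteine with
#' `p_far = 0.02`.
#'
#' @param n_proteins Number of proteins.
#' @param tm_count Integer vector of admissible TM-segment counts
#'   (sampled uniformly).
#' @param loop_len,tm_len,signal_len,intramem_len Inclusive length
#'   ranges per segment kind.
#' @param signal_rate,intramem_rate Per-protein probabilities of
#'   carrying a signal peptide / an intramembrane segment.
#' @param cys_rate Named per-kind cysteine emission rates.
#' @param d_near,p_near,p_far Planted label rule (see above).
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_proteins = 500L,
                         tm_count = 1:4,
                         loop_len = c(10L, 80L),
                         tm_len = c(18L, 25L),
                         signal_len = c(15L, 25L),
                         intramem_len = c(8L, 12L),
                         signal_rate = 0.05,
                         intramem_rate = 0.02,
                         cys_rate = c(Transmembrane = 0.02,
                                      Cytoplasmic = 0.05,
                                      Extracellular = 0.03,
                                      Signal = 0.02,
                                      Intramembrane = 0.02),
                         d_near = 10L, p_near = 0.8, p_far = 0.02) {
  stopifnot(n_proteins >= 1, all(tm_count >= 1),
            d_near >= 0, p_near >= 0, p_near <= 1,
            p_far >= 0, p_far <= 1,
            all(cys_rate >= 0), all(cys_rate < 1))
  structure(list(
    n_proteins = as.integer(n_proteins), tm_count = as.integer(tm_count),
    loop_len = as.integer(loop_len), tm_len = as.integer(tm_len),
    signal_len = as.integer(signal_len),
    intramem_len = as.integer(intramem_len),
    signal_rate = signal_rate, intramem_rate = intramem_rate,
    cys_rate = cys_rate,
    d_near = as.integer(d_near), p_near = p_near, p_far = p_far
  ), class = "synth_params")
}

.sample_len <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

.sample_segment_seq <- function(kind, len, params) {
  comp <- switch(kind,
    Transmembrane = .COMPOSITION$Transmembrane,
    Signal = .COMPOSITION$Signal,
    Intramembrane = .COMPOSITION$Transmembrane,
    .COMPOSITION$Loop
  )
  cr <- unname(params$cys_rate[kind])
  probs <- c(comp * (1 - cr), C = cr)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate one synthetic protein record
#'
#' Alternating extramembrane/transmembrane topology with
#' composition-sampled residues; optionally a signal peptide at the
#' N-terminus and an intramembrane segment split out of an interior
#' loop. Draws from the current RNG state: seed via
#' [generate_proteome()].
#'
#' @param params A [synth_params()].
#' @param accession Identifier for the record.
#' @return A validated [protein_record()].
#' @export
generate_protein <- function(params, accession = "SYN0001") {
  n_tm <- if (length(params$tm_count) == 1L) params$tm_count else
    sample(params$tm_count, 1L)
  side <- sample(c("Cytoplasmic", "Extracellular"), 1L)
  kinds <- character(0)
  if (stats::runif(1) < params$signal_rate) kinds <- "Signal"
  for (i in seq_len(n_tm)) {
    kinds <- c(kinds, side, "Transmembrane")
    side <- if (side == "Cytoplasmic") "Extracellular" else "Cytoplasmic"
  }
  kinds <- c(kinds, side)
  lens <- vapply(kinds, function(k) {
    switch(k,
      Transmembrane = .sample_len(params$tm_len),
      Signal = .sample_len(params$signal_len),
      .sample_len(params$loop_len))
  }, integer(1))
  # optionally carve an intramembrane segment out of one interior loop
  if (stats::runif(1) < params$intramem_rate) {
    loops <- which(kinds %in% c("Cytoplasmic", "Extracellular"))
    il <- .sample_len(params$intramem_len)
    loops <- loops[lens[loops] >= il + 4L]
    if (length(loops) > 0L) {
      j <- if (length(loops) == 1L) loops else sample(loops, 1L)
      left <- 2L
      right <- lens[j] - il - left
      kinds <- append(kinds, c("Intramembrane", kinds[j]), after = j)
      lens <- append(lens, c(il, right), after = j)
      lens[j] <- left
    }
  }
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seqs <- vapply(seq_along(kinds), function(i) {
    .sample_segment_seq(kinds[i], lens[i], params)
  }, character(1))
  seg <- assign_tm_orientation(
    segment_table(kinds, starts, ends))
  protein_record(accession, paste(seqs, collapse = ""), seg,
                 species = "synthetic")
}

#' Generate a synthetic proteome
#'
#' @param params A [synth_params()].
#' @param seed Integer seed; a fixed seed yields a bit-identical
#'   proteome across runs.
#' @return Named list of [protein_record()].
#' @export
generate_proteome <- function(params = synth_params(), seed = 1L) {
  set.seed(seed)
  acc <- sprintf("SYN%04d", seq_len(params$n_proteins))
  stats::setNames(lapply(acc, function(a) generate_protein(params, a)),
                  acc)
}

#' Plant palmitoylation labels on a synthetic proteome
#'
#' Each inference-eligible cysteine whose interface distance is at
#' most `d_near` becomes positive with probability `p_near`, any
#' other with probability `p_far`. The latent rule uses only the
#' interface distance.
#'
#' @param proteome From [generate_proteome()].
#' @param params A [synth_params()].
#' @param seed Integer seed for the label draws.
#' @return List with `truth` (tibble `accession`, `position`, `label`,
#'   `interface_distance`, `near`), `features` and `excluded` from
#'   [featurize_proteome()].
#' @export
plant_labels <- function(proteome, params = synth_params(), seed = 1L) {
  fz <- featurize_proteome(proteome)
  feats <- fz$features
  set.seed(seed)
  near <- feats$interface_distance <= params$d_near
  p <- ifelse(near, params$p_near, params$p_far)
  label <- ifelse(stats::runif(nrow(feats)) < p, "positive", "negative")
  list(
    truth = tibble::tibble(
      accession = feats$accession, position = feats$position,
      label = label, interface_distance = feats$interface_distance,
      near = near),
    features = feats,
    excluded = fz$excluded
  )
}

#' Export a synthetic fixture as on-disk input files
#'
#' Writes the FASTA, the UniProt-style topology table, a
#' SwissPalm-style sites file holding the planted positives (with
#' `site_techniques = "Point mutation"` so the curation filter retains
#' them), and the full truth table. Files round-trip through
#' [read_proteome()] / [filter_sites()] to reproduce the planted
#' positives exactly.
#'
#' @param proteome From [generate_proteome()].
#' @param truth Truth tibble from [plant_labels()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
export_fixture <- function(proteome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteome.fasta"),
    topology = file.path(dir, "topology.tsv"),
    sites = file.path(dir, "sites.csv"),
    truth = file.path(dir, "truth.csv")
  )
  seqs <- Biostrings::AAStringSet(
    vapply(proteome, function(p) p$sequence, character(1)))
  names(seqs) <- vapply(proteome, function(p) p$accession, character(1))
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])
  ann <- dplyr::bind_rows(lapply(proteome, function(p) {
    f <- format_uniprot_features(p$segments)
    tibble::tibble(
      Entry = p$accession, Species = p$species,
      "Transmembrane" = f[["Transmembrane"]],
      "Topological domain" = f[["Topological domain"]],
      "Intramembrane" = f[["Intramembrane"]],
      "Signal peptide" = f[["Signal peptide"]]
    )
  }))
  utils::write.table(ann, paths[["topology"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pos <- truth[truth$label == "positive", , drop = FALSE]
  sites <- tibble::tibble(
    accession = pos$accession, position = pos$position,
    site_techniques = "Point mutation", species = "synthetic")
  utils::write.csv(sites, paths[["sites"]], row.names = FALSE)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
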