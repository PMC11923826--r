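# The 28-feature description of a transmembrane-protein cysteine:
# where the residue sits in the annotated topology (segment offsets,
# membrane-interface distance, termini distances) and what its local
# +/-5-residue windows look like physicochemically (hydropathy,
# charge, polarity, aliphatic index, transmembrane tendency, cysteine
# clustering, basic and asparagine counts). Featurization is a pure
# function of the protein record: no randomness anywhere.

#' The feature registry
#'
#' The fixed, ordered roster of the 28 model features with their types.
#' Categorical features are encoded through the integer registries
#' [TOPOLOGY_KIND_LEVELS] and [TM_ORIENTATION_LEVELS] so fitted models
#' serialize portably.
#'
#' @return Tibble with columns `name`, `type`
#'   (`categorical` / `integer` / `numeric`).
#' @export
feature_registry <- function() {
  tibble::tibble(
    name = c(
      "topology_kind", "tm_orientation",
      "segment_length", "dist_segment_start", "dist_segment_end",
      "rel_position_in_segment", "interface_distance",
      "protein_length", "dist_N_term", "dist_C_term",
      "rel_position_in_protein",
      "window_cys_score",
      "kd_mean_N", "kd_mean_C", "kd_sum", "kd_gradient",
      "charge_N", "charge_C", "charge_gradient",
      "polarity_N", "polarity_C",
      "aliphatic_N", "aliphatic_C",
      "tmtend_N", "tmtend_C",
      "window_basic_count", "window_asn_count",
      "tm_segment_count"
    ),
    type = c(
      "categorical", "categorical",
      "integer", "integer", "integer",
      "numeric", "integer",
      "integer", "integer", "integer",
      "numeric",
      "numeric",
      "numeric", "numeric", "numeric", "numeric",
      "numeric", "numeric", "numeric",
      "numeric", "numeric",
      "numeric", "numeric",
      "numeric", "numeric",
      "integer", "integer",
      "integer"
    )
  )
}

#' Categorical encoding registries
#'
#' Fixed category-to-integer maps used when building model matrices.
#' @export
TOPOLOGY_KIND_LEVELS <- c(Cytoplasmic = 1L, Extracellular = 2L,
                          Transmembrane = 3L)

#' @rdname TOPOLOGY_KIND_LEVELS
#' @export
TM_ORIENTATION_LEVELS <- c(none = 0L, inward = 1L, outward = 2L,
                           unknown = 3L)

#' Distance-decay weights of the window cysteine score
#'
#' A cysteine at window offset d (1 = adjacent to the scored Cys)
#' contributes `(6 - d) / 5` points; offsets run 1..5.
#' @export
CYS_SCORE_WEIGHTS <- (6 - 1:5) / 5

#' Locate a position within the annotated topology
#'
#' @param position Residue position (1-based).
#' @param segments A [segment_table()].
#' @return List with `index` (row in `segments`), `kind`,
#'   `orientation`, `dist_start = position - start`,
#'   `dist_end = end - position`, `length`, and
#'   `rel = dist_start / (length - 1)` (0 for a length-1 segment).
#'   `NULL` when the position falls in a gap between annotated
#'   segments (such sites are not inference-eligible).
#' @export
locate_topology <- function(position, segments) {
  i <- which(segments$start <= position & segments$end >= position)
  if (length(i) != 1L) return(NULL)
  len <- segments$end[i] - segments$start[i] + 1L
  ds <- position - segments$start[i]
  list(
    index = i,
    kind = segments$kind[i],
    orientation = segments$orientation[i],
    dist_start = ds,
    dist_end = segments$end[i] - position,
    length = len,
    rel = if (len == 1L) 0 else ds / (len - 1)
  )
}

#' Residue distance to the membrane interface
#'
#' For a cysteine inside a transmembrane segment the distance is
#' counted to the cytoplasmic end of the helix (`end - position` for
#' inward, `position - start` for outward; the minimum of the two when
#' the orientation is unknown). For a cysteine in an extramembrane
#' segment the distance is counted from the first residue of the
#' segment on its transmembrane-adjacent side: `end - position` for a
#' head (segment followed by a TM), `position - start` for a tail
#' (preceded by a TM), and the minimum of the two for an internal
#' loop. When no adjacent segment is transmembrane (e.g. a loop
#' bordered by a signal peptide) the distance falls back to the
#' nearest transmembrane boundary in the protein.
#'
#' @param position Residue position.
#' @param segments A [segment_table()]; must contain >= 1 TM segment.
#' @param loc Optional precomputed [locate_topology()] result.
#' @return Non-negative integer distance, or `NA` if the position is
#'   unlocatable.
#' @export
interface_distance <- function(position, segments, loc = NULL) {
  if (is.null(loc)) loc <- locate_topology(position, segments)
  if (is.null(loc)) return(NA_integer_)
  if (loc$kind == "Transmembrane") {
    return(switch(loc$orientation,
      inward = loc$dist_end,
      outward = loc$dist_start,
      min(loc$dist_start, loc$dist_end)
    ))
  }
  i <- loc$index
  prev_tm <- i > 1L &&
    segments$kind[i - 1L] == "Transmembrane" &&
    segments$end[i - 1L] == segments$start[i] - 1L
  next_tm <- i < nrow(segments) &&
    segments$kind[i + 1L] == "Transmembrane" &&
    segments$start[i + 1L] == segments$end[i] + 1L
  d <- c(
    if (prev_tm) loc$dist_start,
    if (next_tm) loc$dist_end
  )
  if (length(d) > 0L) return(min(d))
  tm <- segments[segments$kind == "Transmembrane", , drop = FALSE]
  if (nrow(tm) == 0L) return(NA_integer_)
  min(pmax(tm$start - position, position - tm$end, 0L))
}

#' Extract the flanking residue windows of a position
#'
#' Up to `k` residues on each side, truncated at the protein termini;
#' the central residue belongs to neither window.
#'
#' @param sequence Protein sequence.
#' @param position Central residue position.
#' @param k Window width per side (default 5).
#' @return List with `n_window` (N-terminal side, N-to-C order) and
#'   `c_window`.
#' @export
extract_windows <- function(sequence, position, k = 5L) {
  n <- nchar(sequence)
  stopifnot(position >= 1L, position <= n)
  list(
    n_window = substr(sequence, max(1L, position - k), position - 1L),
    c_window = substr(sequence, position + 1L, min(n, position + k))
  )
}

#' Window cysteine-clustering score
#'
#' Awards points for cysteines inside the flanking windows, decaying
#' linearly with distance from the scored residue: a window Cys at
#' offset d contributes `(6 - d) / 5` (see [CYS_SCORE_WEIGHTS]), so an
#' immediately adjacent Cys adds 1.0 and one at the window edge 0.2.
#' Captures the cooperative clustering of palmitoylation sites.
#'
#' @param n_window,c_window Window strings from [extract_windows()].
#' @param weights Offset weight vector (offset 1 first).
#' @return Non-negative score; 0 when no window cysteine.
#' @export
window_cys_score <- function(n_window, c_window,
                             weights = CYS_SCORE_WEIGHTS) {
  k <- length(weights)
  score_side <- function(win, reversed) {
    if (!nzchar(win)) return(0)
    res <- .split_residues(win)
    # offset from the central residue: last char of the N window is 1
    off <- if (reversed) rev(seq_along(res)) else seq_along(res)
    sum(weights[off[res == "C" & off <= k]])
  }
  score_side(n_window, reversed = TRUE) +
    score_side(c_window, reversed = FALSE)
}

#' Hydropathy window block
#'
#' Mean Kyte-Doolittle hydropathy of each window plus their sum
#' (absolute level) and C-minus-N difference (gradient; positive means
#' hydrophobicity increases toward the C-terminus).
#'
#' @inheritParams window_cys_score
#' @return Named list `kd_mean_N`, `kd_mean_C`, `kd_sum`,
#'   `kd_gradient`; an empty window contributes `NA`.
#' @export
hydropathy_block <- function(n_window, c_window) {
  mN <- if (nzchar(n_window)) as.numeric(kd_mean(n_window)) else NA_real_
  mC <- if (nzchar(c_window)) as.numeric(kd_mean(c_window)) else NA_real_
  list(kd_mean_N = mN, kd_mean_C = mC,
       kd_sum = mC + mN, kd_gradient = mC - mN)
}

#' Physicochemical window block
#'
#' Per-side net charge, mean polarity, aliphatic index and mean
#' transmembrane tendency, plus basic-residue (K+R) and asparagine
#' counts pooled over both windows.
#'
#' @inheritParams window_cys_score
#' @return Named list of the ten property features.
#' @export
property_block <- function(n_window, c_window) {
  side <- function(win) {
    if (!nzchar(win)) {
      return(list(charge = NA_real_, polarity = NA_real_,
                  aliphatic = NA_real_, tmtend = NA_real_))
    }
    list(
      charge = as.numeric(net_charge(win)),
      polarity = as.numeric(polarity_mean(win)),
      aliphatic = as.numeric(aliphatic_index(win)),
      tmtend = as.numeric(tm_tendency_mean(win))
    )
  }
  nN <- side(n_window); cC <- side(c_window)
  both <- paste0(n_window, c_window)
  count_of <- function(aa) {
    if (!nzchar(both)) 0L else sum(.split_residues(both) %in% aa)
  }
  list(
    charge_N = nN$charge, charge_C = cC$charge,
    charge_gradient = cC$charge - nN$charge,
    polarity_N = nN$polarity, polarity_C = cC$polarity,
    aliphatic_N = nN$aliphatic, aliphatic_C = cC$aliphatic,
    tmtend_N = nN$tmtend, tmtend_C = cC$tmtend,
    window_basic_count = count_of(c("K", "R")),
    window_asn_count = count_of("N")
  )
}

# Featurize one site. Returns a one-row tibble, or a character reason
# why the site is not inference-eligible.
featurize_site <- function(protein, position, k = 5L) {
  segments <- protein$segments
  if (!any(segments$kind == "Transmembrane")) {
    return("no transmembrane segment")
  }
  loc <- locate_topology(position, segments)
  if (is.null(loc)) return("position in unannotated region")
  if (loc$kind == "Signal") return("signal peptide")
  if (loc$kind == "Intramembrane") return("intramembrane segment")
  win <- extract_windows(protein$sequence, position, k)
  if (!nzchar(win$n_window) && !nzchar(win$c_window)) {
    return("both windows empty")
  }
  touched <- paste0(win$n_window,
                    substr(protein$sequence, position, position),
                    win$c_window)
  if (.has_nonstandard(.split_residues(touched))) {
    return("nonstandard residue in window")
  }
  L <- nchar(protein$sequence)
  hyd <- hydropathy_block(win$n_window, win$c_window)
  prop <- property_block(win$n_window, win$c_window)
  tibble::tibble(
    accession = protein$accession,
    position = as.integer(position),
    topology_kind = loc$kind,
    tm_orientation = if (loc$kind == "Transmembrane") {
      loc$orientation
    } else {
      "none"
    },
    segment_length = as.integer(loc$length),
    dist_segment_start = as.integer(loc$dist_start),
    dist_segment_end = as.integer(loc$dist_end),
    rel_position_in_segment = loc$rel,
    interface_distance = as.integer(
      interface_distance(position, segments, loc)),
    protein_length = as.integer(L),
    dist_N_term = as.integer(position - 1L),
    dist_C_term = as.integer(L - position),
    rel_position_in_protein = if (L == 1L) 0 else (position - 1) / (L - 1),
    window_cys_score = window_cys_score(win$n_window, win$c_window),
    kd_mean_N = hyd$kd_mean_N, kd_mean_C = hyd$kd_mean_C,
    kd_sum = hyd$kd_sum, kd_gradient = hyd$kd_gradient,
    charge_N = prop$charge_N, charge_C = prop$charge_C,
    charge_gradient = prop$charge_gradient,
    polarity_N = prop$polarity_N, polarity_C = prop$polarity_C,
    aliphatic_N = prop$aliphatic_N, aliphatic_C = prop$aliphatic_C,
    tmtend_N = prop$tmtend_N, tmtend_C = prop$tmtend_C,
    window_basic_count = as.integer(prop$window_basic_count),
    window_asn_count = as.integer(prop$window_asn_count),
    tm_segment_count = sum(segments$kind == "Transmembrane")
  )
}

#' Featurize every cysteine of one protein
#'
#' @param protein A [protein_record()].
#' @param k Window width per side.
#' @return List with `features` (tibble, one row per inference-eligible
#'   Cys) and `excluded` (tibble `accession`, `position`, `reason`).
#' @export
featurize_protein <- function(protein, k = 5L) {
  cys <- unlist(gregexpr("C", protein$sequence, fixed = TRUE))
  cys <- as.integer(cys[cys > 0])
  rows <- list(); excl <- list()
  for (p in cys) {
    r <- featurize_site(protein, p, k)
    if (is.character(r)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        accession = protein$accession, position = p, reason = r)
    } else {
      rows[[length(rows) + 1L]] <- r
    }
  }
  list(features = dplyr::bind_rows(rows),
       excluded = dplyr::bind_rows(excl))
}

#' Featurize a proteome
#'
#' One row per inference-eligible cysteine, in deterministic
#' (accession, position) order. Cysteines in signal peptides,
#' intramembrane segments or unannotated gaps, and windows touching
#' nonstandard residues, are excluded with a logged reason --
#' exclusions are data, not failures.
#'
#' @param proteins Named list of [protein_record()].
#' @param k Window width per side.
#' @return List with `features` and `excluded` tibbles.
#' @export
featurize_proteome <- function(proteins, k = 5L) {
  per <- lapply(proteins, featurize_protein, k = k)
  feats <- dplyr::bind_rows(lapply(per, `[[`, "features"))
  excl <- dplyr::bind_rows(lapply(per, `[[`, "excluded"))
  if (nrow(feats) > 0L) {
    feats <- feats[order(feats$accession, feats$position), , drop = FALSE]
  }
  if (nrow(excl) > 0L) {
    excl <- excl[order(excl$accession, excl$position), , drop = FALSE]
  }
  list(features = feats, excluded = excl)
}
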