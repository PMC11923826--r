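# In-silico trypsinization and peptide-level "detectability": the
# mass/hydropathy box that bottom-up proteomics can realistically see,
# and the membrane-proximity census of cysteine-containing peptides.

#' In-silico tryptic digest of one sequence
#'
#' Cleaves on the C-terminal side of every Lys or Arg except when the
#' next residue is Pro. Complete digestion is modelled by default;
#' `missed_cleavages > 0` additionally returns peptides spanning up to
#' that many internal cleavage sites.
#'
#' @param sequence Nonempty residue string.
#' @param missed_cleavages Number of missed cleavages to include
#'   (default 0, complete digestion).
#' @return Tibble with columns `start`, `end` (1-based inclusive),
#'   `sequence`, in N-to-C order.
#' @export
digest_trypsin <- function(sequence, missed_cleavages = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      !nzchar(sequence)) {
    stop("digest_trypsin() requires a nonempty sequence")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  cut_after <- unlist(gregexpr("[KR](?!P)", sequence, perl = TRUE))
  cut_after <- cut_after[cut_after > 0 & cut_after < n]
  bounds <- c(0L, as.integer(cut_after), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  out <- tibble::tibble(
    start = starts, end = ends,
    sequence = substring(sequence, starts, ends)
  )
  if (missed_cleavages > 0L && length(starts) > 1L) {
    extra <- list()
    for (m in seq_len(missed_cleavages)) {
      i <- seq_len(length(starts) - m)
      if (length(i) == 0L) break
      extra[[m]] <- tibble::tibble(
        start = starts[i], end = ends[i + m],
        sequence = substring(sequence, starts[i], ends[i + m])
      )
    }
    out <- dplyr::bind_rows(out, dplyr::bind_rows(extra))
    out <- out[order(out$start, out$end), , drop = FALSE]
  }
  out
}

#' Is a peptide inside the detectability box?
#'
#' The box spans 700 to 3000 Da and mean Kyte-Doolittle hydropathy -2
#' to +1, both bounds inclusive -- a coarse model of what trypsin-based
#' LC-MS recovers well.
#'
#' @param mass Peptide mass, Da.
#' @param mean_kd Mean Kyte-Doolittle hydropathy.
#' @param mass_range,kd_range Inclusive bounds of the box.
#' @return Logical (`NA` when either input is `NA`).
#' @export
detectable <- function(mass, mean_kd,
                       mass_range = c(700, 3000),
                       kd_range = c(-2, 1)) {
  mass >= mass_range[1] & mass <= mass_range[2] &
    mean_kd >= kd_range[1] & mean_kd <= kd_range[2]
}

#' Is a cysteine membrane-proximal?
#'
#' True when the residue lies inside a transmembrane segment (distance
#' 0) or within `cutoff` residues of the nearest transmembrane
#' boundary, counting a residue immediately beyond the boundary as
#' distance 1.
#'
#' @param position Residue position (1-based).
#' @param segments A [segment_table()].
#' @param cutoff Distance cutoff in residues (default 20).
#' @return Logical; `FALSE` with a warning if the protein has no
#'   transmembrane segment.
#' @export
membrane_proximal <- function(position, segments, cutoff = 20L) {
  tm <- segments[segments$kind == "Transmembrane", , drop = FALSE]
  if (nrow(tm) == 0L) {
    warning("membrane_proximal(): no transmembrane segment")
    return(FALSE)
  }
  d <- pmax(tm$start - position, position - tm$end, 0L)
  min(d) <= cutoff
}

#' Digest one protein and annotate its Cys-containing peptides
#'
#' @param protein A [protein_record()].
#' @param site_positions Optional integer positions (protein
#'   coordinates) of reported palmitoylation sites on this protein.
#' @param proximity_cutoff Passed to [membrane_proximal()].
#' @param missed_cleavages Passed to [digest_trypsin()].
#' @return Tibble of Cys-containing peptides: `accession`, `start`,
#'   `end`, `sequence`, `mass`, `mean_kd`, `n_cys`, `cys_positions`
#'   (list column, protein coordinates), `detectable`,
#'   `membrane_proximal`, `reported_palmitoyl`. Peptides containing
#'   nonstandard residues carry `NA` mass/hydropathy and `NA` flags.
#' @export
digest_protein <- function(protein, site_positions = integer(),
                           proximity_cutoff = 20L,
                           missed_cleavages = 0L) {
  peps <- digest_trypsin(protein$sequence, missed_cleavages)
  cys_pos <- lapply(seq_len(nrow(peps)), function(i) {
    off <- unlist(gregexpr("C", peps$sequence[i], fixed = TRUE))
    off <- off[off > 0]
    as.integer(peps$start[i] + off - 1L)
  })
  keep <- lengths(cys_pos) > 0L
  peps <- peps[keep, , drop = FALSE]
  cys_pos <- cys_pos[keep]
  if (nrow(peps) == 0L) {
    return(tibble::tibble(
      accession = character(), start = integer(), end = integer(),
      sequence = character(), mass = double(), mean_kd = double(),
      n_cys = integer(), cys_positions = list(),
      detectable = logical(), membrane_proximal = logical(),
      reported_palmitoyl = logical()
    ))
  }
  mass <- vapply(peps$sequence, function(s) {
    if (.has_nonstandard(.split_residues(s))) NA_real_ else peptide_mass(s)
  }, numeric(1), USE.NAMES = FALSE)
  mkd <- vapply(peps$sequence, function(s) as.numeric(kd_mean(s)),
                numeric(1), USE.NAMES = FALSE)
  has_tm <- any(protein$segments$kind == "Transmembrane")
  prox <- vapply(cys_pos, function(pp) {
    if (!has_tm) return(FALSE)
    any(vapply(pp, membrane_proximal, logical(1),
               segments = protein$segments, cutoff = proximity_cutoff))
  }, logical(1))
  tibble::tibble(
    accession = protein$accession,
    start = peps$start, end = peps$end, sequence = peps$sequence,
    mass = mass, mean_kd = mkd,
    n_cys = lengths(cys_pos), cys_positions = cys_pos,
    detectable = detectable(mass, mkd),
    membrane_proximal = prox,
    reported_palmitoyl = vapply(cys_pos, function(pp) {
      any(pp %in% site_positions)
    }, logical(1))
  )
}

#' Digest a whole proteome
#'
#' @param proteins Named list of [protein_record()].
#' @param sites Optional site table with columns `accession`,
#'   `position` marking reported palmitoylation sites.
#' @inheritParams digest_protein
#' @return Row-bound tibble of [digest_protein()] outputs.
#' @export
digest_proteome <- function(proteins, sites = NULL,
                            proximity_cutoff = 20L,
                            missed_cleavages = 0L) {
  dplyr::bind_rows(lapply(proteins, function(p) {
    sp <- if (is.null(sites)) {
      integer()
    } else {
      as.integer(sites$position[sites$accession == p$accession])
    }
    digest_protein(p, sp, proximity_cutoff, missed_cleavages)
  }))
}

#' Detectability fractions by group
#'
#' For each level of the grouping flag, the count of Cys-containing
#' peptides and the fraction inside the detectability box.
#'
#' @param peptides Output of [digest_proteome()].
#' @param grouping `"reported_palmitoyl"` or `"membrane_proximal"`.
#' @return Tibble `group`, `n`, `n_detectable`, `fraction_detectable`,
#'   ordered by `group` (FALSE then TRUE); empty input gives an empty
#'   table.
#' @export
summarize_detectability <- function(peptides,
                                    grouping = c("reported_palmitoyl",
                                                 "membrane_proximal")) {
  grouping <- match.arg(grouping)
  if (nrow(peptides) == 0L) {
    return(tibble::tibble(group = logical(), n = integer(),
                          n_detectable = integer(),
                          fraction_detectable = double()))
  }
  g <- peptides[[grouping]]
  ok <- !is.na(g) & !is.na(peptides$detectable)
  peptides <- peptides[ok, , drop = FALSE]
  g <- g[ok]
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = g,
                                   detectable = peptides$detectable),
                    group),
    n = dplyr::n(),
    n_detectable = sum(detectable),
    fraction_detectable = mean(detectable),
    .groups = "drop"
  )
  out[order(out$group), , drop = FALSE]
}
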