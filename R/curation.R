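# Building the labeled training table: filter a SwissPalm-style
# "Sites" export down to rigorously evidenced positives, merge
# supplemental positive lists, and infer the negative class as every
# other inference-eligible cysteine on the same proteins. Negatives
# are never drawn from proteins without a positive, which keeps
# unstudied proteins out of the negative class.

#' Read a SwissPalm-style sites table
#'
#' @param path Delimited file (comma or tab, sniffed from the header)
#'   with at least columns `accession`, `position`, `site_techniques`,
#'   `species`.
#' @return Tibble of site rows.
#' @export
read_sites_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Filter a sites table down to rigorously evidenced positives
#'
#' Keeps rows whose `site_techniques` text contains any of the
#' technique terms (plain substring, case-sensitive by default --
#' matching the literal SwissPalm strings), then applies an optional
#' species allowlist, then deduplicates on (accession, position).
#'
#' @param sites Tibble with columns `accession`, `position`,
#'   `site_techniques`, `species`.
#' @param technique_terms Substrings accepted as evidence (default the
#'   site-directed-mutagenesis / radiolabeling terms
#'   `"Point mutation"` and `"palmitate"`).
#' @param species_allowlist Optional character vector of allowed
#'   species labels.
#' @param ignore_case Match technique terms case-insensitively (for
#'   other SwissPalm dialects).
#' @return Tibble `accession`, `position`, `species`, `source`
#'   (= `"swisspalm"`), one row per site.
#' @export
filter_sites <- function(sites,
                         technique_terms = c("Point mutation", "palmitate"),
                         species_allowlist = NULL,
                         ignore_case = FALSE) {
  req <- c("accession", "position", "site_techniques", "species")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols) > 0L) {
    stop("sites table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  hay <- sites$site_techniques
  if (ignore_case) {
    hay <- tolower(hay)
    technique_terms <- tolower(technique_terms)
  }
  hit <- rep(FALSE, nrow(sites))
  for (term in technique_terms) {
    hit <- hit | grepl(term, hay, fixed = TRUE)
  }
  out <- sites[hit, , drop = FALSE]
  if (!is.null(species_allowlist)) {
    out <- out[out$species %in% species_allowlist, , drop = FALSE]
  }
  out <- tibble::tibble(
    accession = as.character(out$accession),
    position = as.integer(out$position),
    species = as.character(out$species),
    source = "swisspalm"
  )
  out[!duplicated(out[c("accession", "position")]), , drop = FALSE]
}

#' Filter a (site, palmitoyl fraction) supplement file
#'
#' Helper for native-MS style supplements quantifying the
#' palmitoylated fraction per site: keeps sites whose fraction is
#' strictly greater than the threshold.
#'
#' @param tbl Tibble with columns `accession`, `position`, `fraction`.
#' @param threshold Strict lower bound on the palmitoylated fraction
#'   (default 0.25).
#' @return Tibble `accession`, `position`.
#' @export
filter_palmitoyl_fraction <- function(tbl, threshold = 0.25) {
  stopifnot(all(c("accession", "position", "fraction") %in% names(tbl)))
  keep <- tbl$fraction > threshold
  tibble::tibble(accession = as.character(tbl$accession[keep]),
                 position = as.integer(tbl$position[keep]))
}

#' Merge supplemental positive lists into the curated positives
#'
#' Supplements may only add positives, never remove; duplicates of an
#' existing (accession, position) leave the set unchanged. Every
#' positive keeps exactly one source tag (first writer wins, curated
#' positives first).
#'
#' @param positives Curated positives from [filter_sites()].
#' @param ... Supplement tibbles with columns `accession`, `position`
#'   and optionally `source`; unnamed sources default to
#'   `"supplement"`.
#' @param proteome Optional named list of [protein_record()]; when
#'   given, a supplement position beyond the protein length is an
#'   error naming the row.
#' @return Tibble `accession`, `position`, `source`.
#' @export
merge_supplements <- function(positives, ..., proteome = NULL) {
  sups <- list(...)
  out <- tibble::tibble(accession = as.character(positives$accession),
                        position = as.integer(positives$position),
                        source = if ("source" %in% names(positives)) {
                          positives$source
                        } else {
                          "swisspalm"
                        })
  for (s in sups) {
    if (nrow(s) == 0L) next
    src <- if ("source" %in% names(s)) s$source else "supplement"
    add <- tibble::tibble(accession = as.character(s$accession),
                          position = as.integer(s$position),
                          source = src)
    if (!is.null(proteome)) {
      for (i in seq_len(nrow(add))) {
        p <- proteome[[add$accession[i]]]
        if (!is.null(p) && add$position[i] > nchar(p$sequence)) {
          stop("supplement position beyond protein length: ",
               add$accession[i], " position ", add$position[i])
        }
      }
    }
    out <- dplyr::bind_rows(out, add)
  }
  out[!duplicated(out[c("accession", "position")]), , drop = FALSE]
}

#' Infer the negative class and assemble the labeled dataset
#'
#' Every inference-eligible cysteine on a protein carrying at least
#' one positive that is not itself a positive becomes a negative.
#' Positives whose protein could not be featurized are dropped with a
#' logged reason; a positive pointing at a non-Cys residue is an error
#' (usually an isoform or coordinate mismatch).
#'
#' @param positives Tibble `accession`, `position`, `source`.
#' @param proteome Named list of [protein_record()] covering the
#'   positive-bearing proteins.
#' @param features Optional precomputed [featurize_proteome()] result
#'   for `proteome` (computed here if omitted).
#' @return List with `dataset` (feature rows + `label` in
#'   `positive`/`negative` + `provenance`), `dropped_positives`
#'   (tibble with reasons) and `report` (per-stage counts, including
#'   the class imbalance).
#' @export
infer_negatives <- function(positives, proteome, features = NULL) {
  if (is.null(features)) features <- featurize_proteome(proteome)
  feats <- if (is.data.frame(features)) features else features$features
  # verify positives point at Cys residues
  for (i in seq_len(nrow(positives))) {
    p <- proteome[[positives$accession[i]]]
    if (is.null(p)) next
    pos <- positives$position[i]
    if (pos <= nchar(p$sequence) &&
        substr(p$sequence, pos, pos) != "C") {
      stop("positive site is not a cysteine: ", positives$accession[i],
           " position ", pos, " (residue ",
           substr(p$sequence, pos, pos), ")")
    }
  }
  key <- function(a, p) paste(a, p, sep = "@")
  pos_key <- key(positives$accession, positives$position)
  feat_key <- key(feats$accession, feats$position)
  matched <- pos_key %in% feat_key
  dropped <- positives[!matched, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    dropped$reason <- ifelse(
      dropped$accession %in% names(proteome),
      "site not inference-eligible",
      "protein absent from proteome")
  } else {
    dropped$reason <- character(0)
  }
  pos_proteins <- unique(positives$accession[matched])
  rows <- feats[feats$accession %in% pos_proteins, , drop = FALSE]
  is_pos <- key(rows$accession, rows$position) %in% pos_key
  rows$label <- ifelse(is_pos, "positive", "negative")
  rows$provenance <- ifelse(
    is_pos,
    positives$source[match(key(rows$accession, rows$position), pos_key)],
    "inferred_negative")
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  list(
    dataset = rows,
    dropped_positives = dropped,
    report = tibble::tibble(
      stage = c("positives_supplied", "positives_matched",
                "positives_dropped", "negatives_inferred",
                "class_imbalance"),
      value = c(nrow(positives), n_pos, nrow(dropped), n_neg,
                if (n_pos > 0) class_imbalance_counts(n_pos, n_neg)
                else NA_real_)
    )
  )
}

#' Class imbalance of a labeled dataset
#'
#' Defined as (positives + negatives) / positives, the total-to-
#' positive ratio; an all-positive dataset gives the lower bound 1.
#'
#' @param dataset Labeled dataset with a `label` column.
#' @return Imbalance ratio (>= 1).
#' @export
class_imbalance <- function(dataset) {
  stopifnot("label" %in% names(dataset))
  class_imbalance_counts(sum(dataset$label == "positive"),
                         sum(dataset$label == "negative"))
}

#' @rdname class_imbalance
#' @param n_pos,n_neg Class counts.
#' @export
class_imbalance_counts <- function(n_pos, n_neg) {
  if (n_pos <= 0) stop("class imbalance undefined without positives")
  (n_pos + n_neg) / n_pos
}
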