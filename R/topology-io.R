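# Reading and validating protein records: FASTA sequences joined with
# UniProt-style topology annotations. All coordinates in this package
# are 1-based inclusive (UniProt convention); every distance and span
# computation elsewhere assumes exactly that.

SEGMENT_KINDS <- c("Cytoplasmic", "Extracellular", "Transmembrane",
                   "Intramembrane", "Signal")

#' Construct a topology segment table
#'
#' @param kind Character vector over
#'   `Cytoplasmic | Extracellular | Transmembrane | Intramembrane | Signal`.
#' @param start,end 1-based inclusive residue coordinates.
#' @param orientation For transmembrane segments: `inward` (C-terminal
#'   side cytoplasmic), `outward`, or `unknown`; always `NA` otherwise.
#' @return A tibble with columns `kind`, `start`, `end`, `orientation`,
#'   sorted by `start`.
#' @export
segment_table <- function(kind, start, end, orientation = NULL) {
  kind <- as.character(kind)
  if (is.null(orientation)) orientation <- rep(NA_character_, length(kind))
  seg <- tibble::tibble(
    kind = kind,
    start = as.integer(start),
    end = as.integer(end),
    orientation = as.character(orientation)
  )
  seg <- seg[order(seg$start), , drop = FALSE]
  validate_segments(seg)
  seg
}

validate_segments <- function(segments, protein_length = NULL,
                              accession = "<unknown>") {
  if (nrow(segments) == 0L) return(invisible(segments))
  if (!all(segments$kind %in% SEGMENT_KINDS)) {
    bad <- setdiff(unique(segments$kind), SEGMENT_KINDS)
    stop("unknown segment kind(s) for ", accession, ": ",
         paste(bad, collapse = ", "))
  }
  if (any(segments$start < 1L) || any(segments$end < segments$start)) {
    stop("invalid segment span for ", accession,
         " (need 1 <= start <= end)")
  }
  if (!is.null(protein_length) && any(segments$end > protein_length)) {
    stop("segment beyond sequence length for ", accession)
  }
  if (is.unsorted(segments$start)) {
    stop("segments must be sorted by start for ", accession)
  }
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    stop("overlapping segments for ", accession)
  }
  bad_orient <- !is.na(segments$orientation) &
    segments$kind != "Transmembrane"
  if (any(bad_orient)) {
    stop("orientation set on non-transmembrane segment for ", accession)
  }
  invisible(segments)
}

#' Construct and validate a protein record
#'
#' The unit every pipeline stage consumes: accession, sequence and an
#' ordered, non-overlapping segment table.
#'
#' @param accession Identifier.
#' @param sequence Amino-acid string; nonstandard letters are accepted
#'   but flagged (`$has_nonstandard`), and sites touching them are later
#'   excluded from inference rather than given fabricated scale values.
#' @param segments A [segment_table()].
#' @param species Species label.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, segments,
                           species = "unknown") {
  sequence <- toupper(sequence)
  stopifnot(is.character(accession), length(accession) == 1L,
            is.character(sequence), nzchar(sequence))
  validate_segments(segments, protein_length = nchar(sequence),
                    accession = accession)
  structure(
    list(
      accession = accession,
      sequence = sequence,
      segments = segments,
      species = species,
      has_nonstandard = .has_nonstandard(.split_residues(sequence))
    ),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s), %d aa, %d segment(s), %d TM\n",
              x$accession, x$species, nchar(x$sequence),
              nrow(x$segments),
              sum(x$segments$kind == "Transmembrane")))
  invisible(x)
}

#' Parse a UniProt-style feature string into spans
#'
#' Accepts the flat UniProt export notation, e.g.
#' `TRANSMEM 51..71; /note="Helical"; TRANSMEM 90..110; /note="Helical"`.
#' Both `..` and `...` span separators are accepted; anything else is
#' rejected.
#'
#' @param text Feature field text (may be empty or `NA` for none).
#' @param accession Used in error messages.
#' @return Tibble with columns `keyword`, `start`, `end`, `note`
#'   (raw label, `NA` when absent), ascending by `start`.
#' @export
parse_uniprot_features <- function(text, accession = "<unknown>") {
  empty <- tibble::tibble(keyword = character(), start = integer(),
                          end = integer(), note = character())
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(trimws(text))) {
    return(empty)
  }
  # split into feature chunks beginning at each keyword
  kw <- "(TRANSMEM|TOPO_DOM|INTRAMEM|SIGNAL)"
  starts <- stringr::str_locate_all(text, kw)[[1]]
  if (nrow(starts) == 0L) {
    stop("no recognizable feature keyword in annotation for ", accession,
         ": '", text, "'")
  }
  chunk_from <- starts[, "start"]
  chunk_to <- c(chunk_from[-1L] - 1L, nchar(text))
  rows <- lapply(seq_along(chunk_from), function(i) {
    chunk <- substr(text, chunk_from[i], chunk_to[i])
    keyword <- stringr::str_match(chunk, kw)[, 2]
    span <- stringr::str_match(chunk,
      paste0("^", kw, "\\s+(\\d+)\\.\\.\\.?(\\d+)"))
    if (is.na(span[1, 1])) {
      stop("malformed span in annotation for ", accession, ": '",
           trimws(chunk), "'")
    }
    s <- as.integer(span[1, 3]); e <- as.integer(span[1, 4])
    if (s > e) {
      stop("inverted span (start > end) in annotation for ", accession,
           ": '", trimws(chunk), "'")
    }
    note <- stringr::str_match(chunk, "/note=\"([^\"]*)\"")[, 2]
    tibble::tibble(keyword = keyword, start = s, end = e, note = note)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$start), , drop = FALSE]
}

#' Canonicalize a raw topology label into a segment kind
#'
#' `Lumenal` and `Stromal` annotations are reclassified as
#' `Extracellular` so categorical levels align across organelles;
#' unrecognized labels raise an error (never a silent coercion).
#'
#' @param raw_label Raw note text, or a feature keyword.
#' @return One of the segment kinds.
#' @export
canonicalize_kind <- function(raw_label) {
  stopifnot(is.character(raw_label), length(raw_label) == 1L)
  lab <- trimws(raw_label)
  if (lab %in% c("Lumenal", "Stromal", "Extracellular")) return("Extracellular")
  if (lab == "Cytoplasmic") return("Cytoplasmic")
  if (lab %in% c("Helical", "TRANSMEM", "Transmembrane")) return("Transmembrane")
  if (lab %in% c("INTRAMEM", "Intramembrane")) return("Intramembrane")
  if (lab %in% c("SIGNAL", "Signal", "Signal peptide")) return("Signal")
  stop("unrecognized topology label: '", raw_label, "'")
}

.kind_from_feature <- function(keyword, note) {
  switch(keyword,
    TRANSMEM = "Transmembrane",
    INTRAMEM = "Intramembrane",
    SIGNAL = "Signal",
    TOPO_DOM = {
      if (is.na(note)) stop("TOPO_DOM without /note label")
      canonicalize_kind(note)
    },
    stop("unknown feature keyword: ", keyword)
  )
}

#' Assign inward/outward orientation to transmembrane segments
#'
#' A transmembrane segment is oriented by the segment immediately
#' preceding it (the one whose `end` equals the TM `start - 1`):
#' preceding Extracellular implies the C-terminal side is cytoplasmic
#' (`inward`); preceding Cytoplasmic implies `outward`; no predecessor,
#' or one of another kind, leaves the orientation `unknown`.
#'
#' @param segments Sorted, non-overlapping [segment_table()].
#' @return Same table with `orientation` filled for TM segments.
#' @export
assign_tm_orientation <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  orientation <- segments$orientation
  for (i in which(segments$kind == "Transmembrane")) {
    prev <- which(segments$end == segments$start[i] - 1L)
    orientation[i] <-
      if (length(prev) == 1L && segments$kind[prev] == "Extracellular") {
        "inward"
      } else if (length(prev) == 1L && segments$kind[prev] == "Cytoplasmic") {
        "outward"
      } else {
        "unknown"
      }
  }
  segments$orientation <- orientation
  segments
}

#' Build segment table from a UniProt tab-export annotation row
#'
#' @param row Named list / one-row data frame with any of the columns
#'   `Transmembrane`, `Topological.domain` (or `Topological domain`),
#'   `Intramembrane`, `Signal.peptide` (or `Signal peptide`).
#' @param accession Used in error messages.
#' @return Canonicalized, oriented [segment_table()].
#' @export
segments_from_annotation <- function(row, accession = "<unknown>") {
  pick <- function(...) {
    for (nm in c(...)) {
      if (!is.null(row[[nm]])) return(row[[nm]])
    }
    NA_character_
  }
  feats <- dplyr::bind_rows(
    parse_uniprot_features(pick("Transmembrane"), accession),
    parse_uniprot_features(pick("Topological.domain", "Topological domain"),
                           accession),
    parse_uniprot_features(pick("Intramembrane"), accession),
    parse_uniprot_features(pick("Signal.peptide", "Signal peptide"),
                           accession)
  )
  if (nrow(feats) == 0L) {
    return(segment_table(character(), integer(), integer()))
  }
  kind <- vapply(seq_len(nrow(feats)), function(i) {
    .kind_from_feature(feats$keyword[i], feats$note[i])
  }, character(1))
  seg <- segment_table(kind, feats$start, feats$end)
  assign_tm_orientation(seg)
}

#' Is a protein eligible for inference?
#'
#' Requires at least one transmembrane segment. Per-site eligibility
#' (annotation gaps, signal peptides, intramembrane regions,
#' nonstandard residues) is decided during featurization.
#'
#' @param protein A [protein_record()].
#' @export
is_inference_eligible <- function(protein) {
  any(protein$segments$kind == "Transmembrane")
}

#' Read a proteome from FASTA plus a topology annotation table
#'
#' Joins sequences and annotations on accession. Proteins lacking a
#' sequence, lacking any topology row, or whose annotation refers to
#' positions beyond the sequence are set aside with a reason rather
#' than dropped silently.
#'
#' @param fasta_path FASTA file of protein sequences; names up to the
#'   first whitespace are taken as accessions.
#' @param annotation_path Tab-separated table with column `Entry` plus
#'   UniProt-style feature columns (see [segments_from_annotation()]).
#' @param species Species label applied to all records (or column
#'   `Species` in the annotation table, if present).
#' @return List with `proteins` (named list of [protein_record()]) and
#'   `excluded` (tibble `accession`, `reason`).
#' @export
read_proteome <- function(fasta_path, annotation_path,
                          species = "unknown") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  names(seqs) <- acc
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           check.names = TRUE, quote = "")
  if (!"Entry" %in% names(ann)) {
    stop("annotation table must have an 'Entry' column")
  }
  if (anyDuplicated(ann$Entry)) {
    stop("duplicate accession(s) in annotation: ",
         paste(unique(ann$Entry[duplicated(ann$Entry)]), collapse = ", "))
  }
  proteins <- list()
  excluded <- list()
  for (a in acc) {
    i <- match(a, ann$Entry)
    if (is.na(i)) {
      excluded[[a]] <- "no topology annotation"
      next
    }
    sp <- if ("Species" %in% names(ann)) ann$Species[i] else species
    rec <- tryCatch(
      protein_record(a, as.character(seqs[[a]]),
                     segments_from_annotation(ann[i, , drop = FALSE], a),
                     species = sp),
      error = function(e) conditionMessage(e)
    )
    if (is.character(rec)) {
      excluded[[a]] <- rec
    } else {
      proteins[[a]] <- rec
    }
  }
  for (a in setdiff(ann$Entry, acc)) {
    excluded[[a]] <- "no sequence in FASTA"
  }
  list(
    proteins = proteins,
    excluded = tibble::tibble(
      accession = names(excluded),
      reason = unlist(excluded, use.names = FALSE)
    )
  )
}

#' Serialize segments back to the UniProt flat notation
#'
#' Inverse of [parse_uniprot_features()] for generator-produced
#' annotations; used by the fixture exporter and round-trip tests.
#'
#' @param segments A [segment_table()].
#' @return Named character vector with elements `Transmembrane`,
#'   `Topological domain`, `Intramembrane`, `Signal peptide` (empty
#'   string when a protein has none of that feature).
#' @export
format_uniprot_features <- function(segments) {
  fmt <- function(keyword, rows, note) {
    if (nrow(rows) == 0L) return("")
    paste(sprintf('%s %d..%d; /note="%s"', keyword, rows$start, rows$end,
                  note(rows)), collapse = "; ")
  }
  c(
    "Transmembrane" = fmt("TRANSMEM",
      segments[segments$kind == "Transmembrane", ],
      function(r) rep("Helical", nrow(r))),
    "Topological domain" = fmt("TOPO_DOM",
      segments[segments$kind %in% c("Cytoplasmic", "Extracellular"), ],
      function(r) r$kind),
    "Intramembrane" = fmt("INTRAMEM",
      segments[segments$kind == "Intramembrane", ],
      function(r) rep("Intramembrane", nrow(r))),
    "Signal peptide" = fmt("SIGNAL",
      segments[segments$kind == "Signal", ],
      function(r) rep("Signal peptide", nrow(r)))
  )
}
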