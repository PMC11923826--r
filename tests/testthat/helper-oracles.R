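# Independent brute-force oracles. These deliberately share no code
# with the implementation paths they check.

# Tryptic digest by walking the sequence one residue at a time.
oracle_digest <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  peptides <- character(0)
  cur <- character(0)
  for (i in seq_len(n)) {
    cur <- c(cur, res[i])
    cleave <- res[i] %in% c("K", "R") && i < n && res[i + 1] != "P"
    if (cleave) {
      peptides <- c(peptides, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  if (length(cur) > 0) peptides <- c(peptides, paste(cur, collapse = ""))
  peptides
}

# Which segment row contains a position (loop, no vectorization).
.oracle_containing <- function(position, segments) {
  for (i in seq_len(nrow(segments))) {
    if (position >= segments$start[i] && position <= segments$end[i]) {
      return(i)
    }
  }
  NA_integer_
}

# Membrane-interface distance by stepping residue-by-residue outward
# until the segment kind changes into (or out of) a transmembrane
# segment.
oracle_interface_distance <- function(position, segments) {
  i <- .oracle_containing(position, segments)
  if (is.na(i)) return(NA_integer_)
  kind_at <- function(p) {
    j <- .oracle_containing(p, segments)
    if (is.na(j)) NA_character_ else segments$kind[j]
  }
  steps_until_tm <- function(dir) {
    k <- 0L
    p <- position
    repeat {
      nxt <- p + dir
      if (nxt < segments$start[1] || nxt > max(segments$end)) {
        return(NA_integer_)
      }
      if (!identical(kind_at(nxt), segments$kind[i])) {
        return(if (identical(kind_at(nxt), "Transmembrane")) k
               else NA_integer_)
      }
      p <- nxt
      k <- k + 1L
    }
  }
  if (segments$kind[i] == "Transmembrane") {
    steps_to_exit <- function(dir) {
      k <- 0L
      p <- position
      while (!is.na(.oracle_containing(p + dir, segments)) &&
             segments$kind[.oracle_containing(p + dir, segments)] ==
               "Transmembrane") {
        p <- p + dir
        k <- k + 1L
      }
      k
    }
    ori <- segments$orientation[i]
    if (identical(ori, "inward")) return(steps_to_exit(+1L))
    if (identical(ori, "outward")) return(steps_to_exit(-1L))
    return(min(steps_to_exit(+1L), steps_to_exit(-1L)))
  }
  d <- c(steps_until_tm(-1L), steps_until_tm(+1L))
  d <- d[!is.na(d)]
  if (length(d) > 0) return(min(d))
  # no adjacent transmembrane neighbour: nearest TM boundary overall
  tm <- segments[segments$kind == "Transmembrane", , drop = FALSE]
  if (nrow(tm) == 0) return(NA_integer_)
  min(pmax(tm$start - position, position - tm$end, 0L))
}

# Confusion-matrix metrics by direct enumeration, no shared code.
oracle_confusion <- function(scores, labels01, threshold) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels01[i] == 1) tp <- tp + 1L
    if (pred && labels01[i] == 0) fp <- fp + 1L
    if (!pred && labels01[i] == 1) fn <- fn + 1L
    if (!pred && labels01[i] == 0) tn <- tn + 1L
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else ((tp * tn) - (fp * fn)) / den
  c(tp = tp, fp = fp, fn = fn, tn = tn,
    precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

random_aa_string <- function(n, alphabet = AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
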