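test_that("locate_topology computes segment offsets and relative position", {
  seg <- toy_protein()$segments
  l1 <- locate_topology(72, seg)
  expect_equal(l1$dist_start, 0L)
  expect_equal(l1$rel, 0)
  l2 <- locate_topology(120, seg)
  expect_equal(l2$dist_end, 0L)
  expect_equal(l2$rel, 1)
  l3 <- locate_topology(96, seg)
  expect_equal(l3$dist_start, 24L)
  expect_equal(l3$dist_end, 24L)
  expect_equal(l3$rel, 0.5)
  # gap between segments -> NULL (site not inference-eligible)
  gap <- segment_table(c("Cytoplasmic", "Transmembrane"),
                       c(1, 20), c(10, 40))
  expect_null(locate_topology(15, gap))
  # degenerate length-1 segment convention
  seg1 <- segment_table(c("Cytoplasmic", "Transmembrane", "Extracellular"),
                        c(1, 2, 23), c(1, 22, 40))
  expect_equal(locate_topology(1, seg1)$rel, 0)
})

test_that("interface distance follows orientation and head/tail conventions", {
  seg <- toy_protein()$segments  # TM 51-71 inward, Cyto tail 72-120
  expect_equal(interface_distance(71, seg), 0L)   # last residue, inward TM
  expect_equal(interface_distance(75, seg), 3L)   # tail: 75 - 72
  expect_equal(interface_distance(51, seg), 20L)  # inward TM start
  expect_equal(interface_distance(40, seg), 10L)  # extracellular head: 50 - 40

  # internal loop flanked by TMs takes the minimum side
  segs <- toy_multipass()$segments  # Extra loop 52-80 flanked by TMs
  expect_equal(interface_distance(57, segs), 5L)   # min(57-52, 80-57) = 5
  expect_equal(interface_distance(75, segs), 5L)   # min(23, 5)
  # outward TM measures from its start
  expect_equal(interface_distance(35, segs), 4L)   # TM 31-51 outward
})

test_that("interface distance matches the scan-outward oracle on random synthetic sites", {
  params <- synth_params(n_proteins = 60)
  proteome <- generate_proteome(params, seed = 77)
  checked <- 0L
  for (p in proteome) {
    L <- nchar(p$sequence)
    set.seed(L + checked)
    for (pos in sample(L, min(L, 20))) {
      loc <- locate_topology(pos, p$segments)
      if (is.null(loc) ||
          loc$kind %in% c("Signal", "Intramembrane")) next
      expect_equal(interface_distance(pos, p$segments),
                   oracle_interface_distance(pos, p$segments),
                   info = paste(p$accession, pos))
      checked <- checked + 1L
    }
    if (checked >= 1000L) break
  }
  expect_gte(checked, 1000L)
})

test_that("windows truncate at termini and never contain the central residue", {
  s <- paste(rep("A", 300), collapse = "")
  w <- extract_windows(s, 100)
  expect_equal(nchar(w$n_window), 5L)
  expect_equal(nchar(w$c_window), 5L)
  w2 <- extract_windows(s, 3)
  expect_equal(nchar(w2$n_window), 2L)
  w3 <- extract_windows(s, 1)
  expect_equal(w3$n_window, "")
  expect_equal(nchar(w3$c_window), 5L)
  w4 <- extract_windows(s, 300)
  expect_equal(w4$c_window, "")
})

test_that("window Cys score decays linearly with offset", {
  expect_equal(window_cys_score("AAAAA", "AAAAA"), 0)
  expect_equal(window_cys_score("AAAAC", "CAAAA"), 2.0)  # offset 1 both sides
  expect_equal(window_cys_score("CAAAA", "AAAAA"), 0.2)  # offset 5
  expect_equal(window_cys_score("AAAAA", "AAAAC"), 0.2)
  expect_equal(window_cys_score("AACAA", "AAAAA"), 0.6)  # offset 3
  # truncated window keeps offsets anchored at the central residue
  expect_equal(window_cys_score("CA", ""), 0.8)          # offset 2
  expect_equal(window_cys_score("", "AC"), 0.8)
})

test_that("hydropathy block computes sum and C-minus-N gradient", {
  h <- hydropathy_block("IIIII", "RRRRR")
  expect_equal(h$kd_mean_N, 4.5)
  expect_equal(h$kd_mean_C, -4.5)
  expect_equal(h$kd_sum, 0.0)
  expect_equal(h$kd_gradient, -9.0)
  h2 <- hydropathy_block("LLLLL", "LLLLL")
  expect_equal(h2$kd_gradient, 0)
  # mirror identity: reversing the protein negates the gradient
  s <- "MKTAYICAKQRQISFVKSHFSRQLEER"
  pos <- 7L
  rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rpos <- nchar(s) - pos + 1L
  w <- extract_windows(s, pos); rw <- extract_windows(rs, rpos)
  expect_equal(hydropathy_block(w$n_window, w$c_window)$kd_gradient,
               -hydropathy_block(rw$n_window, rw$c_window)$kd_gradient)
})

test_that("property block applies each scale per side plus pooled counts", {
  p <- property_block("KKKKK", "EEEEE")
  expect_equal(p$charge_N, 5)
  expect_equal(p$charge_C, -5)
  expect_equal(p$charge_gradient, -10)
  expect_equal(p$window_basic_count, 5L)
  p2 <- property_block("ANNAA", "AAAAN")
  expect_equal(p2$window_asn_count, 3L)
  g <- property_block("GGGGG", "GGGGG")
  pol <- aa_scale("polarity"); tmt <- aa_scale("tm_tendency")
  expect_equal(g$polarity_N, unname(pol["G"]))
  expect_equal(g$tmtend_C, unname(tmt["G"]))
  expect_equal(g$aliphatic_N, 0)
})

test_that("featurize_proteome yields one row per eligible Cys with logged exclusions", {
  # signal-peptide and intramembrane cysteines are excluded, the rest kept
  res <- rep("A", 100)
  res[c(5L, 30L, 60L, 80L)] <- "C"
  seg <- assign_tm_orientation(segment_table(
    c("Signal", "Extracellular", "Transmembrane", "Intramembrane",
      "Cytoplasmic"),
    c(1, 11, 41, 55, 71), c(10, 40, 54, 70, 100)))
  p <- protein_record("SIG1", paste(res, collapse = ""), seg)
  out <- featurize_proteome(list(SIG1 = p))
  expect_equal(out$features$position, c(30L, 80L))
  expect_setequal(out$excluded$reason,
                  c("signal peptide", "intramembrane segment"))

  # a protein with no Cys contributes no rows
  res2 <- rep("A", 60)
  p2 <- protein_record("NOC", paste(res2, collapse = ""),
                       assign_tm_orientation(segment_table(
                         c("Cytoplasmic", "Transmembrane", "Extracellular"),
                         c(1, 21, 42), c(20, 41, 60))))
  expect_equal(nrow(featurize_protein(p2)$features), 0L)

  # nonstandard residue inside a window excludes only that site
  res3 <- rep("A", 60); res3[30] <- "C"; res3[32] <- "X"; res3[10] <- "C"
  p3 <- protein_record("NS1", paste(res3, collapse = ""),
                       assign_tm_orientation(segment_table(
                         c("Cytoplasmic", "Transmembrane", "Extracellular"),
                         c(1, 21, 42), c(20, 41, 60))))
  out3 <- featurize_protein(p3)
  expect_equal(out3$features$position, 10L)
  expect_equal(out3$excluded$reason, "nonstandard residue in window")
})

test_that("feature rows satisfy the bookkeeping identities and are deterministic", {
  params <- synth_params(n_proteins = 25)
  proteome <- generate_proteome(params, seed = 55)
  f1 <- featurize_proteome(proteome)$features
  f2 <- featurize_proteome(proteome)$features
  expect_identical(f1, f2)  # pure function, no randomness
  expect_gt(nrow(f1), 0L)
  expect_equal(f1$dist_segment_start + f1$dist_segment_end,
               f1$segment_length - 1L)
  expect_equal(f1$dist_N_term + f1$dist_C_term, f1$protein_length - 1L)
  expect_true(all(f1$rel_position_in_segment >= 0 &
                    f1$rel_position_in_segment <= 1))
  expect_true(all(f1$interface_distance >= 0))
  expect_identical(f1$accession, sort(f1$accession))
  # registry covers exactly the feature columns
  reg <- feature_registry()
  expect_equal(nrow(reg), 28L)
  expect_true(all(reg$name %in% names(f1)))
})
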