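test_that("UniProt feature strings parse into 1-based inclusive spans", {
  f <- parse_uniprot_features("TRANSMEM 51..71")
  expect_equal(nrow(f), 1L)
  expect_equal(f$start, 51L)
  expect_equal(f$end, 71L)
  expect_equal(f$keyword, "TRANSMEM")

  f2 <- parse_uniprot_features('TOPO_DOM 1..50; /note="Lumenal"')
  expect_equal(f2$note, "Lumenal")
  expect_equal(c(f2$start, f2$end), c(1L, 50L))

  # triple-dot dialect is accepted; spans come back ascending
  f3 <- parse_uniprot_features(
    'TRANSMEM 90...110; /note="Helical"; TRANSMEM 51..71; /note="Helical"')
  expect_equal(f3$start, c(51L, 90L))

  expect_error(parse_uniprot_features("TRANSMEM 71..51", "P1"),
               "inverted span.*P1")
  expect_error(parse_uniprot_features("TRANSMEM ab..cd", "P1"),
               "malformed span")
  expect_equal(nrow(parse_uniprot_features("")), 0L)
  expect_equal(nrow(parse_uniprot_features(NA_character_)), 0L)
})

test_that("raw topology labels canonicalize with errors on unknowns", {
  expect_equal(canonicalize_kind("Lumenal"), "Extracellular")
  expect_equal(canonicalize_kind("Stromal"), "Extracellular")
  expect_equal(canonicalize_kind("Cytoplasmic"), "Cytoplasmic")
  expect_equal(canonicalize_kind("Helical"), "Transmembrane")
  expect_error(canonicalize_kind("Mitochondrial intermembrane"),
               "unrecognized")
})

test_that("TM orientation follows the preceding segment", {
  seg <- assign_tm_orientation(segment_table(
    c("Extracellular", "Transmembrane", "Cytoplasmic"),
    c(1, 51, 72), c(50, 71, 120)))
  expect_equal(seg$orientation[seg$kind == "Transmembrane"], "inward")

  seg2 <- assign_tm_orientation(segment_table(
    c("Cytoplasmic", "Transmembrane", "Extracellular"),
    c(1, 11, 32), c(10, 31, 60)))
  expect_equal(seg2$orientation[seg2$kind == "Transmembrane"], "outward")

  # N-terminal TM with no predecessor stays unknown
  seg3 <- assign_tm_orientation(segment_table(
    c("Transmembrane", "Cytoplasmic"), c(1, 22), c(21, 60)))
  expect_equal(seg3$orientation[1], "unknown")

  # alternating multipass: consecutive TM orientations alternate
  p <- toy_multipass()
  ori <- p$segments$orientation[p$segments$kind == "Transmembrane"]
  expect_equal(ori, c("outward", "inward"))

  # orientation is a pure function of adjacency: shuffled feature order
  # in the annotation string gives the same orientations
  ann <- list(
    Transmembrane = 'TRANSMEM 81..101; /note="Helical"; TRANSMEM 31..51; /note="Helical"',
    Topological.domain = 'TOPO_DOM 52..80; /note="Extracellular"; TOPO_DOM 1..30; /note="Cytoplasmic"; TOPO_DOM 102..140; /note="Cytoplasmic"'
  )
  seg4 <- segments_from_annotation(ann)
  expect_equal(seg4$orientation[seg4$kind == "Transmembrane"],
               c("outward", "inward"))
})

test_that("protein records validate their segment bookkeeping", {
  expect_error(
    protein_record("P1", "ACDEF",
                   segment_table("Transmembrane", 1, 10)),
    "beyond sequence length")
  expect_error(
    segment_table(c("Cytoplasmic", "Transmembrane"), c(1, 5), c(10, 20)),
    "overlapping")
  expect_error(segment_table("Weird", 1, 10), "unknown segment kind")
})

test_that("read_proteome joins FASTA and annotation with logged exclusions", {
  dir <- withr::local_tempdir()
  writeLines(c(">P1", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQC",
               ">P2", "ACDEFGHIKLMNPQRSTVWY",
               ">P3", "AAAACAAAA"),
             file.path(dir, "p.fasta"))
  writeLines(c("Entry\tTransmembrane\tTopological domain",
               paste0("P1\tTRANSMEM 10..30; /note=\"Helical\"\t",
                      "TOPO_DOM 1..9; /note=\"Cytoplasmic\"; ",
                      "TOPO_DOM 31..34; /note=\"Extracellular\""),
               "P2\tTRANSMEM 5..200; /note=\"Helical\"\t"),
             file.path(dir, "ann.tsv"))
  out <- read_proteome(file.path(dir, "p.fasta"),
                       file.path(dir, "ann.tsv"))
  expect_equal(names(out$proteins), "P1")
  expect_equal(sort(out$excluded$accession), c("P2", "P3"))
  expect_match(out$excluded$reason[out$excluded$accession == "P2"],
               "beyond sequence length")
  expect_match(out$excluded$reason[out$excluded$accession == "P3"],
               "no topology annotation")

  # duplicate accession in FASTA is a hard error
  writeLines(c(">P1", "ACDEF", ">P1", "ACDEF"),
             file.path(dir, "dup.fasta"))
  expect_error(read_proteome(file.path(dir, "dup.fasta"),
                             file.path(dir, "ann.tsv")),
               "duplicate accession")
})

test_that("generator annotations round-trip bit-exactly through the parser", {
  params <- synth_params(n_proteins = 15)
  proteome <- generate_proteome(params, seed = 301)
  truth <- plant_labels(proteome, params, seed = 302)$truth
  dir <- withr::local_tempdir()
  paths <- export_fixture(proteome, truth, dir)
  back <- read_proteome(paths[["fasta"]], paths[["topology"]])
  expect_equal(nrow(back$excluded), 0L)
  expect_setequal(names(back$proteins), names(proteome))
  for (a in names(proteome)) {
    expect_identical(back$proteins[[a]]$sequence, proteome[[a]]$sequence)
    expect_identical(
      as.data.frame(back$proteins[[a]]$segments),
      as.data.frame(proteome[[a]]$segments))
  }
})
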