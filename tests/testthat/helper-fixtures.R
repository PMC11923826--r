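# Deterministic toy proteins and the shared (memoized) reference
# simulation used by the model-recovery and design-scan tests.

# Single-pass protein: Extracellular 1-50, TM 51-71 (inward),
# Cytoplasmic 72-120. Cysteines planted at known positions.
toy_protein <- function(cys_at = c(40L, 60L, 75L, 96L, 120L)) {
  res <- rep("A", 120)
  res[51:71] <- "L"
  res[cys_at] <- "C"
  seg <- assign_tm_orientation(segment_table(
    c("Extracellular", "Transmembrane", "Cytoplasmic"),
    c(1L, 51L, 72L), c(50L, 71L, 120L)))
  protein_record("TOY1", paste(res, collapse = ""), seg,
                 species = "synthetic")
}

# Multipass alternating protein for orientation / loop tests:
# Cyto 1-30, TM 31-51 (outward), Extra 52-80, TM 81-101 (inward),
# Cyto 102-140.
toy_multipass <- function(cys_at = integer()) {
  res <- rep("G", 140)
  res[c(31:51, 81:101)] <- "I"
  res[cys_at] <- "C"
  seg <- assign_tm_orientation(segment_table(
    c("Cytoplasmic", "Transmembrane", "Extracellular", "Transmembrane",
      "Cytoplasmic"),
    c(1L, 31L, 52L, 81L, 102L), c(30L, 51L, 80L, 101L, 140L)))
  protein_record("TOY2", paste(res, collapse = ""), seg,
                 species = "synthetic")
}

# The reference simulation: 500 proteins, planted rule
# d_near = 10, p_near = 0.8, p_far = 0.02, protein-level 3:1
# train/test split, default hyperparameters. Built once per test run.
.fixture_env <- new.env(parent = emptyenv())

reference_fit <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  params <- synth_params()
  proteome <- generate_proteome(params, seed = 11)
  planted <- plant_labels(proteome, params, seed = 12)
  ds <- planted$features
  ds$label <- planted$truth$label
  accs <- unique(ds$accession)
  set.seed(13)
  test_acc <- sample(accs, length(accs) %/% 4)
  train <- ds[!ds$accession %in% test_acc, , drop = FALSE]
  test <- ds[ds$accession %in% test_acc, , drop = FALSE]
  model <- train_palm_model(train, palm_hyperparams(seed = 5), cv = FALSE)
  scores <- predict_palm(model, test)
  .fixture_env$fx <- list(
    params = params, proteome = proteome, planted = planted,
    train = train, test = test, test_acc = test_acc,
    model = model, scores = scores)
  .fixture_env$fx
}
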