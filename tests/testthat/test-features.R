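test_that("modulo folding sets exactly the residue bits", {
  v <- hash_fingerprint_indices(0, 4096)
  expect_equal(which(v == 1), 1)  # bit 0
  v <- hash_fingerprint_indices(4096, 4096)
  expect_equal(which(v == 1), 1)  # 4096 mod 4096 = 0
  v <- hash_fingerprint_indices(c(5000, 904), 4096)
  expect_equal(sum(v), 1)
  expect_equal(which(v == 1) - 1, 904)
  expect_equal(sum(hash_fingerprint_indices(integer(0), 64)), 0)
  expect_error(hash_fingerprint_indices(-1, 64), "nonnegative")
})

test_that("folding matches the explicit per-index modulo construction", {
  set.seed(77)
  for (i in 1:1000) {
    idx <- sample(0:(2^20), sample(1:40, 1), replace = TRUE)
    got <- hash_fingerprint_indices(idx, 4096)
    want <- integer(4096)
    for (j in idx) want[(j %% 4096) + 1] <- 1L  # brute-force loop
    expect_identical(got, want)
    # pure function of the index multiset: order/multiplicity irrelevant
    expect_identical(hash_fingerprint_indices(rev(rep(idx, 2)), 4096), got)
    expect_lte(sum(got), length(unique(idx)))
  }
})

test_that("the default descriptor list has 97 unique names", {
  expect_length(default_descriptors(), 97)
  expect_false(anyDuplicated(default_descriptors()) > 0)
  cfg <- descriptor_config()
  expect_equal(cfg$fingerprint_bits, 4096)
  expect_equal(cfg$fingerprint_radius, 2)
  expect_error(descriptor_config(descriptor_names = character(0)),
               "nonempty")
  expect_error(descriptor_config(descriptor_names = c("MW", "MW")),
               "duplicate|nonempty")
  expect_error(descriptor_config(descriptor_names = "no_such_descriptor"),
               "unknown")
})

test_that("descriptor matrices are 97 wide, deterministic, with failures reported", {
  skip_if_not_installed("ChemmineR")
  smi <- c("CCO", "c1ccccc1O", "not_a_smiles", "CC(=O)Oc1ccccc1C(=O)O")
  m <- compute_descriptors(smi)
  expect_equal(ncol(m), 97)
  expect_equal(nrow(m), 3)  # the bad record is dropped, not imputed
  fails <- attr(m, "failures")
  expect_equal(fails$smiles, "not_a_smiles")
  expect_equal(fails$index, 3)
  # determinism
  m2 <- compute_descriptors(c("CCO", "CCO"))
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
  # sanity on known molecules: ethanol has 2 C, 1 O, no ring
  expect_equal(unname(m["mol1", "n_C"]), 2)
  expect_equal(unname(m["mol1", "n_O"]), 1)
  expect_equal(unname(m["mol1", "n_rings"]), 0)
  # phenol: one 6-ring, 6 ring atoms
  expect_equal(unname(m["mol2", "n_rings"]), 1)
  expect_equal(unname(m["mol2", "n_ring_atoms"]), 6)
  expect_equal(unname(m["mol2", "largest_ring"]), 6)
  expect_error(compute_descriptors("not_a_smiles"), "parsed")
  # a configured subset controls width and order
  cfg <- descriptor_config(descriptor_names = c("MW", "n_rings", "n_C"))
  m3 <- compute_descriptors("c1ccccc1", cfg)
  expect_equal(colnames(m3), c("MW", "n_rings", "n_C"))
})

test_that("circular fingerprints are binary, bounded and deterministic", {
  skip_if_not_installed("ChemmineR")
  smi <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O")
  fp <- morgan_fingerprints(smi, descriptor_config(fingerprint_bits = 512))
  expect_equal(dim(fp), c(2, 512))
  expect_true(all(fp %in% c(0L, 1L)))
  raw1 <- morgan_indices(smi[1])
  expect_identical(raw1, morgan_indices(smi[1]))
  expect_lte(sum(fp[1, ]), length(unique(raw1)))
  # folded vector equals folding the raw indices directly
  expect_identical(unname(fp[1, ]), hash_fingerprint_indices(raw1, 512))
  # different molecules give different fingerprints
  expect_false(identical(fp[1, ], fp[2, ]))
  expect_null(morgan_indices("not_a_smiles"))
})

test_that("SMILES files are read in CSV and plain layouts", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,label", "a,CCO,active",
               "b,c1ccccc1,inactive"), csv)
  df <- read_smiles(csv)
  expect_equal(df$compound_id, c("a", "b"))
  expect_equal(df$label, c("active", "inactive"))
  plain <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol_a", "c1ccccc1"), plain)
  df2 <- read_smiles(plain)
  expect_equal(df2$smiles, c("CCO", "c1ccccc1"))
  expect_equal(df2$compound_id[1], "mol_a")
})

test_that("the standardisation hook is a configurable pass-through", {
  expect_equal(standardize_smiles(c("CCO")), "CCO")
  expect_equal(standardize_smiles("CCO", toupper), "CCO")
  expect_equal(standardize_smiles("cco", function(s) toupper(s)), "CCO")
})
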