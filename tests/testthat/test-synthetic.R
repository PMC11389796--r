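test_that("planted property follows the atom-count formula", {
  expect_equal(planted_property("CCO"), 0.4)        # 1 - 0.3 * 2
  expect_equal(planted_property("CCCCC"), -1.5)     # pure carbon chain
  expect_equal(planted_property("NO"), 2)
  expect_equal(planted_property("ClCCl"), -0.3)     # Cl carries no weight
})

test_that("generated molecules are valid, sized, and deterministic", {
  recs <- generate_molecules(60, seed = 2)
  expect_equal(nrow(recs), 60L)
  expect_false(anyNA(recs$y))
  for (i in seq_len(nrow(recs))) {
    s <- recs$smiles[i]
    expect_true(is_valid_smiles(s))
    mol <- parse_smiles(s)
    expect_true(mol$n_atoms >= 5 && mol$n_atoms <= 16)
    expect_true(all(mol$atoms$symbol %in% c("C", "N", "O", "Cl")))
    expect_equal(recs$y_true[i], planted_property(s))
    expect_equal(recs$y[i], mean(recs$replicates[[i]]))
    expect_equal(recs$n_measurements[i], length(recs$replicates[[i]]))
    if (recs$n_measurements[i] > 1) {
      expect_equal(recs$y_std[i], stats::sd(recs$replicates[[i]]))
    } else {
      expect_true(is.na(recs$y_std[i]))
    }
  }
  # a healthy share of molecules carries replicate measurements and rings
  expect_gt(mean(recs$n_measurements > 1), 0.3)
  expect_gt(mean(vapply(recs$smiles, function(s) grepl("1", s), logical(1))), 0.2)
  # same seed -> identical records; different seed -> different molecules
  expect_identical(generate_molecules(60, seed = 2)$smiles, recs$smiles)
  expect_false(identical(generate_molecules(60, seed = 3)$smiles, recs$smiles))
})

test_that("random split partitions molecules with ~10% test", {
  recs <- generate_molecules(50, seed = 4)
  sp <- split_dataset(recs, "random", seed = 1)
  expect_s3_class(sp, "split_manifest")
  expect_length(sp$test_idx, ceiling(0.1 * 50))
  expect_length(sp$folds, 3L)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_length(intersect(c(f$train, f$validation), sp$test_idx), 0L)
    expect_setequal(c(f$train, f$validation, sp$test_idx), 1:50)
  }
  expect_identical(split_dataset(recs, "random", seed = 1)$test_idx, sp$test_idx)
})

test_that("accurate split filters by replication and uncertainty, order-independently", {
  recs <- generate_molecules(80, seed = 5)
  sp <- split_dataset(recs, "accurate", seed = 9)
  expect_length(sp$folds, 5L)
  expect_true(all(recs$n_measurements[sp$test_idx] > 1))
  expect_true(all(recs$y_std[sp$test_idx] <= 0.2))
  outside <- setdiff(seq_len(nrow(recs)), sp$test_idx)
  expect_true(all(recs$n_measurements[outside] == 1 |
                    is.na(recs$y_std[outside]) | recs$y_std[outside] > 0.2))
  # membership is a pure filter: reordering rows permutes it consistently
  perm <- rev(seq_len(nrow(recs)))
  sp2 <- split_dataset(recs[perm, ], "accurate", seed = 1)
  expect_setequal(perm[sp2$test_idx], sp$test_idx)
  # no qualifying record -> explicit error
  solo <- recs; solo$n_measurements <- 1L; solo$y_std <- NA_real_
  expect_error(split_dataset(solo, "accurate"), "accurate filter")
})

test_that("scaffold split never straddles a framework across train and test", {
  recs <- generate_molecules(70, seed = 6)
  sp <- split_dataset(recs, "scaffold", test_fraction = 0.2, seed = 3)
  keys <- vapply(recs$smiles, scaffold_key, character(1))
  test_keys <- unique(keys[sp$test_idx])
  train_all <- setdiff(seq_len(nrow(recs)), sp$test_idx)
  expect_length(intersect(test_keys, unique(keys[train_all])), 0L)
  expect_gte(length(sp$test_idx), ceiling(0.2 * nrow(recs)))
})

test_that("read_dataset handles full and minimal schemas and reports totals", {
  recs <- generate_molecules(20, seed = 7)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(recs[, c("smiles", "y", "n_measurements", "y_std")], path,
                   row.names = FALSE)
  ds <- read_dataset(path)
  expect_equal(ds$smiles, recs$smiles)
  expect_equal(ds$y, recs$y)
  rp <- attr(ds, "report")
  expect_equal(rp$n_rows, 20L)
  expect_equal(rp$n_molecules, length(unique(recs$smiles)))
  expect_equal(rp$total_measurements, sum(recs$n_measurements))

  # minimal schema: counts default to 1, sd to NA
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(smiles = c("CCO", "CCN"), y = c(0.4, 0.7)),
                   path2, row.names = FALSE)
  ds2 <- read_dataset(path2)
  expect_equal(ds2$n_measurements, c(1L, 1L))
  expect_true(all(is.na(ds2$y_std)))
  expect_equal(attr(ds2, "report")$total_measurements, 2L)

  # missing required column -> named in the error
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(structure_ = "CCO", val = 1), path3, row.names = FALSE)
  expect_error(read_dataset(path3), "smiles")
  ds3 <- read_dataset(path3, smiles_col = "structure_", target_col = "val")
  expect_equal(ds3$smiles, "CCO")
})

test_that("an independent chemistry toolkit agrees on validity and atom counts", {
  recs <- generate_molecules(30, seed = 8)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    print(-1 if m is None else m.GetNumAtoms())"
  ), script)
  out <- system2("python3", script, stdout = TRUE,
                 input = recs$smiles, stderr = FALSE)
  counts <- as.integer(out)
  expect_true(all(counts > 0))        # every generated SMILES parses there too
  expect_equal(counts,
               vapply(recs$smiles, function(s) parse_smiles(s)$n_atoms,
                      integer(1), USE.NAMES = FALSE))
})
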