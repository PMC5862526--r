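make_ct <- function(mouse, structure, experience, timepoint, group, gene,
                    ct) {
  data.frame(mouse_id = mouse, structure = structure,
             experience = experience, timepoint_hr = timepoint,
             control_group_id = group, gene = gene, ct = ct,
             stringsAsFactors = FALSE)
}

test_that("global reference Ct is the arithmetic mean of reference genes", {
  ct <- make_ct("m1", "s1", "a", 1, "g", c("r1", "r2", "Arc"),
                c(18, 22, 25))
  ref <- global_reference_ct(ct, reference_genes = c("r1", "r2"))
  expect_equal(ref$ref_ct, 20)
  expect_equal(ref$n_ref, 2L)

  # 8 reference genes all at Ct 20 -> 20
  ct8 <- make_ct("m1", "s1", "a", 1, "g", paste0("r", 1:8), rep(20, 8))
  expect_equal(global_reference_ct(ct8, paste0("r", 1:8))$ref_ct, 20)
})

test_that("global reference matches a direct row-mean computation", {
  set.seed(5)
  genes <- paste0("r", 1:8)
  mice <- paste0("m", 1:6)
  ct <- do.call(rbind, lapply(mice, function(m) {
    make_ct(m, "s1", "a", 1, "g", genes, runif(8, 15, 25))
  }))
  ref <- global_reference_ct(ct, genes)
  direct <- vapply(mice, function(m) mean(ct$ct[ct$mouse_id == m]), 0)
  expect_equal(ref$ref_ct[match(mice, ref$mouse_id)], unname(direct),
               tolerance = 1e-12)
})

test_that("a sample without reference genes is named in the error", {
  ct <- rbind(make_ct("m1", "s1", "a", 1, "g", c("r1", "Arc"), c(20, 22)),
              make_ct("m2", "s1", "a", 1, "g", "Arc", 23))
  expect_error(global_reference_ct(ct, "r1"), "m2")
})

test_that("delta-Ct subtracts the reference and drops reference genes", {
  ct <- make_ct("m1", "s1", "a", 1, "g", c("r1", "Arc"), c(20, 22))
  dct <- delta_ct(ct, mode = "global", reference = "r1")
  expect_equal(dct$dct[dct$gene == "Arc"], 2)
  expect_false("r1" %in% dct$gene)

  # a gene normalized to itself would sit at delta-Ct 0
  ct2 <- make_ct("m1", "s1", "a", 1, "g", c("Gapdh", "Arc"), c(20, 22))
  d2 <- delta_ct(ct2, mode = "single_gene", reference = "Gapdh")
  expect_equal(d2$dct[d2$gene == "Arc"], 2)
  ref_self <- ct2$ct[ct2$gene == "Gapdh"] - 20
  expect_equal(ref_self, 0)
})

test_that("global mode with a singleton reference set equals single-gene mode", {
  set.seed(6)
  ct <- do.call(rbind, lapply(paste0("m", 1:4), function(m) {
    make_ct(m, "s1", "a", 1, "g", c("Gapdh", "Arc", "Fos"),
            runif(3, 18, 26))
  }))
  g <- delta_ct(ct, "global", reference = "Gapdh")
  s <- delta_ct(ct, "single_gene", reference = "Gapdh")
  expect_equal(g, s)
})

test_that("fold induction implements 2^-(ddCt) against the control mean", {
  # treated sample at dCt 2 vs control group mean dCt 3 -> fold 2
  dct <- data.frame(
    mouse_id = c("t1", "c1", "c2"), structure = "s1",
    experience = "a", timepoint_hr = c(1, 0, 0),
    control_group_id = "ctrl_a", gene = "Arc",
    dct = c(2, 2.5, 3.5), stringsAsFactors = FALSE)
  f <- fold_induction(dct)
  expect_equal(f$fold[f$mouse_id == "t1"], 2)
  # a control sitting exactly at its group mean has fold 1
  dct$dct[3] <- 2.5
  f2 <- fold_induction(dct)
  expect_equal(f2$fold[f2$mouse_id == "c1"], 1)
  expect_equal(f2$fold[f2$mouse_id == "c2"], 1)
})

test_that("empty control groups are reported by (group, structure, gene)", {
  dct <- data.frame(mouse_id = "t1", structure = "s1", experience = "a",
                    timepoint_hr = 1, control_group_id = "ctrl_a",
                    gene = "Arc", dct = 2, stringsAsFactors = FALSE)
  expect_error(fold_induction(dct), "no control rows")
  dct2 <- rbind(dct, data.frame(mouse_id = "c1", structure = "s2",
                                experience = "a", timepoint_hr = 0,
                                control_group_id = "ctrl_a", gene = "Arc",
                                dct = 1, stringsAsFactors = FALSE))
  expect_error(fold_induction(dct2), "ctrl_a s1 Arc")
})

test_that("control-group folds have geometric mean 1 on synthetic data", {
  cfg <- sim_config(n_per_class = 4, seed = 21)
  sim <- generate_ct_dataset(cfg)
  folds <- fold_induction(delta_ct(sim$ct))
  ctrl <- folds[folds$timepoint_hr == 0, ]
  gm <- aggregate(fold ~ control_group_id + structure + gene, data = ctrl,
                  FUN = function(v) exp(mean(log(v))))
  expect_true(all(abs(gm$fold - 1) < 1e-10))
})

test_that("log2 of fold recovers -ddCt exactly (round trip)", {
  cfg <- sim_config(n_per_class = 3, seed = 22)
  sim <- generate_ct_dataset(cfg)
  dct <- delta_ct(sim$ct)
  folds <- fold_induction(dct)
  ctrl_mean <- aggregate(dct ~ control_group_id + structure + gene,
                         data = dct[dct$timepoint_hr == 0, ], FUN = mean)
  key <- paste(dct$control_group_id, dct$structure, dct$gene)
  ddct <- dct$dct - ctrl_mean$dct[match(key, paste(ctrl_mean$control_group_id,
                                                   ctrl_mean$structure,
                                                   ctrl_mean$gene))]
  expect_equal(log2(folds$fold), -ddct, tolerance = 1e-12)
})

test_that("a constant Ct shift of one sample cancels under normalization", {
  cfg <- sim_config(n_per_class = 3, seed = 23)
  sim <- generate_ct_dataset(cfg)
  ct <- sim$ct
  shifted <- ct
  pick <- shifted$mouse_id == ct$mouse_id[1] &
    shifted$structure == ct$structure[1]
  shifted$ct[pick] <- shifted$ct[pick] + 3.7
  f1 <- fold_induction(delta_ct(ct))
  f2 <- fold_induction(delta_ct(shifted))
  expect_equal(f1$fold, f2$fold, tolerance = 1e-10)
})

test_that("feature assembly applies the transform and missing policy", {
  folds <- rbind(
    fold_row("m1", "Arc", "LCtx", "a", 2),
    fold_row("m1", "Arc", "NAc", "a", 4),
    fold_row("m2", "Arc", "LCtx", "a", 8),
    fold_row("m2", "Arc", "NAc", "a", 1))
  fm <- assemble_features(folds, genes = "Arc",
                          structures = c("LCtx", "NAc"))
  expect_equal(unname(fm$x["m1", "Arc_LCtx"]), 1)  # log2(2)
  expect_equal(unname(fm$x["m2", "Arc_LCtx"]), 3)
  expect_equal(ncol(fm$x), 2)

  # a mouse missing one structure is dropped, the rest intact
  folds3 <- rbind(folds, fold_row("m3", "Arc", "LCtx", "a", 2))
  fm3 <- assemble_features(folds3, genes = "Arc",
                           structures = c("LCtx", "NAc"))
  expect_setequal(rownames(fm3$x), c("m1", "m2"))
  expect_equal(attr(fm3, "dropped"), "m3")
  expect_error(
    assemble_features(folds3, genes = "Arc",
                      structures = c("LCtx", "NAc"),
                      missing_policy = "strict"),
    "m3")
  fi <- assemble_features(folds3, genes = "Arc",
                          structures = c("LCtx", "NAc"),
                          missing_policy = "impute")
  expect_equal(unname(fi$x["m3", "Arc_NAc"]), 0)  # log2(fold 1)
})

test_that("default assembly yields the 5 x 5 = 25 feature panel", {
  cfg <- sim_config(n_per_class = 2, seed = 24)
  sim <- generate_ct_dataset(cfg)
  fm <- normalize_ct(sim$ct)
  expect_equal(ncol(fm$x), 25)
  expect_equal(nrow(fm$x), 20)  # treated mice only
})
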