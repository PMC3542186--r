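hdac_classes <- setNames(hdac_panel()$hdac_class, hdac_panel()$target_id)

test_that("the selectivity rule reproduces the reference calls", {
  apicidin <- c(HDAC2 = 0.238, HDAC8 = 0.096, HDAC4 = -0.501,
                HDAC7 = -0.176, HDAC6 = -0.120)
  expect_equal(as.character(call_selectivity(apicidin, hdac_classes)),
               "class_I_selective")
  nct10a <- c(HDAC2 = -0.405, HDAC8 = -0.731, HDAC4 = 0.137,
              HDAC7 = 0.159, HDAC6 = 0.010)
  expect_equal(as.character(call_selectivity(nct10a, hdac_classes)),
               "class_II_selective")
  lbh <- c(HDAC2 = 0.742, HDAC8 = 0.391, HDAC4 = 0.524, HDAC7 = 0.347,
           HDAC6 = 0.996)
  expect_equal(as.character(call_selectivity(lbh, hdac_classes)), "pan")
  # a single active isoform is called before class selectivity
  mgcd <- c(HDAC2 = 0.296, HDAC8 = -0.946, HDAC4 = -0.557,
            HDAC7 = -1.018, HDAC6 = -0.963)
  expect_equal(as.character(call_selectivity(mgcd, hdac_classes)),
               "isoform_selective(HDAC2)")
  prof <- setNames(rep(0.5, 5), names(hdac_classes))
  expect_equal(as.character(call_selectivity(prof, hdac_classes)), "pan")
  expect_equal(as.character(call_selectivity(-prof, hdac_classes)),
               "inactive")
  expect_error(call_selectivity(numeric(0), hdac_classes), "empty")
})

test_that("the margin rule demotes poorly separated profiles to mixed", {
  prof <- c(HDAC2 = 0.05, HDAC8 = 0.04, HDAC4 = -0.01, HDAC7 = -0.3,
            HDAC6 = -0.2)
  expect_equal(as.character(call_selectivity(prof, hdac_classes,
                                             margin = 0.1)), "mixed")
  expect_equal(as.character(call_selectivity(prof, hdac_classes,
                                             margin = 0)),
               "class_I_selective")
})

test_that("calls are invariant to target order and consistent under shifts", {
  apicidin <- c(HDAC2 = 0.238, HDAC8 = 0.096, HDAC4 = -0.501,
                HDAC7 = -0.176, HDAC6 = -0.120)
  perm <- sample(names(apicidin))
  expect_equal(as.character(call_selectivity(apicidin[perm], hdac_classes)),
               as.character(call_selectivity(apicidin, hdac_classes)))
  shift <- 2 * max(abs(apicidin)) + 1
  expect_equal(as.character(call_selectivity(apicidin + shift,
                                             hdac_classes)), "pan")
  expect_equal(as.character(call_selectivity(apicidin - shift,
                                             hdac_classes)), "inactive")
})

test_that("the external-validation report scores label consistency", {
  t6 <- reference_profiles()
  expect_equal(nrow(t6), 10L)
  pred <- as.matrix(t6[, c("HDAC2", "HDAC8", "HDAC4", "HDAC7", "HDAC6")])
  rownames(pred) <- t6$compound_id
  rep6 <- selectivity_report(compounds = t6[, c("compound_id", "label")],
                             predictions = pred, classes = hdac_classes)
  expect_equal(nrow(rep6), 10L)
  bycid <- setNames(rep6$call, rep6$compound_id)
  expect_equal(unname(bycid["Apicidin"]), "class_I_selective")
  expect_equal(unname(bycid["NCT-10a"]), "class_II_selective")
  expect_equal(unname(bycid["LBH589"]), "pan")
  expect_true(rep6$agree[rep6$compound_id == "LBH589"])
  # an isoform call inside the labeled class counts as consistent
  expect_true(rep6$agree[rep6$compound_id == "MGCD0103"])
  ag <- attr(rep6, "agreement")
  expect_true(ag >= 0 && ag <= 1)
  expect_equal(ag, mean(rep6$agree))

  # all-positive profiles labeled pan agree perfectly
  allpos <- matrix(0.5, 2, 5,
                   dimnames = list(c("x", "y"), names(hdac_classes)))
  repp <- selectivity_report(
    compounds = data.frame(compound_id = c("x", "y"), label = "pan"),
    predictions = allpos, classes = hdac_classes)
  expect_equal(attr(repp, "agreement"), 1)
})

test_that("profile prediction assembles one row per panel target", {
  syn <- generate_dataset(synth_config(seed = 13, n_compounds = 50,
                                       pairs_per_target = c(15, 15, 25, 8, 20)))
  rec <- syn$records; rec$split <- "train"
  fit <- pcm(rec, syn$protein_block, syn$ligand_block,
             spec = model_spec("P", "L", "blocks_only"),
             puk = synth_puk(), svr = synth_svr())
  prof <- predict_profile(fit, rownames(syn$ligand_block)[1])
  expect_length(prof, 5L)
  expect_identical(names(prof), rownames(syn$protein_block))
  # duplicated target ids give identical predictions
  prof2 <- predict_profile(fit, rownames(syn$ligand_block)[1],
                           targets = c("T1", "T1", "T2"))
  expect_equal(unname(prof2[1]), unname(prof2[2]))
  # a numeric descriptor vector works too
  prof3 <- predict_profile(fit, syn$ligand_block[1, ])
  expect_equal(unname(prof3), unname(prof))
  expect_error(predict_profile(fit, "nonexistent"), "no ligand")
})
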