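test_that("learning-rate schedule is constant then decays linearly to zero", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(100, cfg), 2e-4)
  expect_equal(lr_schedule(150, cfg), 1e-4)
  expect_equal(lr_schedule(200, cfg), 0)
  expect_error(lr_schedule(201, cfg), "outside")
  expect_error(lr_schedule(-1, cfg), "outside")
  # no-decay edge case
  cfg2 <- train_config(epochs = 10, decay_start_epoch = 10)
  expect_equal(lr_schedule(10, cfg2), 2e-4)
})

test_that("ablation modes map bijectively onto the two switches", {
  expect_length(ablation_modes(), 4)
  flags <- lapply(ablation_modes(), ablation_flags)
  combos <- vapply(flags, function(f)
    paste(f$use_gc, f$use_uncertainty), character(1))
  expect_length(unique(combos), 4)
  expect_true(ablation_flags("withGC_withUnc")$use_gc)
  expect_false(ablation_flags("withoutGC_withoutUnc")$use_uncertainty)
  expect_error(ablation_flags("nope"), "unknown")
})

test_that("one training step updates parameters and respects the switches", {
  ds <- tiny_dataset()
  batch_a <- ds$a; batch_b <- ds$b
  for (mode in ablation_modes()) {
    fl <- ablation_flags(mode)
    cfg <- tiny_config(use_gc = fl$use_gc, use_uncertainty = fl$use_uncertainty)
    set.seed(cfg$seed)
    nets <- init_cyclegan(cfg)
    w_before <- nets$g_ab$params$enc1_conv$W
    d_before <- nets$d_a$params$d1_conv$W
    rep1 <- train_step(batch_a, batch_b, nets, cfg)
    expect_s3_class(rep1, "ucycle_loss_report")
    expect_true(all(is.finite(unlist(rep1[c("l_adv_ct", "l_adv_mr",
                                            "l_cycle", "total")]))))
    expect_false(identical(nets$g_ab$params$enc1_conv$W, w_before))
    expect_false(identical(nets$d_a$params$d1_conv$W, d_before))
    # generator head width follows the uncertainty switch
    expect_identical(nets$g_ab$spec$out_channels, if (fl$use_uncertainty) 2L else 1L)
    if (fl$use_gc) {
      expect_equal(rep1$total,
                   rep1$l_adv_ct + rep1$l_adv_mr + 10 * rep1$l_cycle + 0.5 * rep1$l_gc,
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(rep1$l_gc))
      expect_equal(rep1$total,
                   rep1$l_adv_ct + rep1$l_adv_mr + 10 * rep1$l_cycle,
                   tolerance = 1e-12)
    }
  }
})

test_that("generators move through the adversarial path alone", {
  ds <- tiny_dataset()
  cfg <- tiny_config(weights = loss_weights(0, 0), use_gc = FALSE)
  set.seed(3)
  nets <- init_cyclegan(cfg)
  w_before <- nets$g_ab$params$head_conv$W
  train_step(ds$a, ds$b, nets, cfg)
  expect_false(identical(nets$g_ab$params$head_conv$W, w_before))
})

test_that("fit writes logs and checkpoints, and resuming continues the count", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  cfg <- tiny_config()
  run <- fit(ds$a, ds$b, cfg, out_dir = dir)
  expect_equal(sort(unique(run$log$epoch)), 1:2)
  expect_true(file.exists(file.path(dir, "training_log.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  logged <- utils::read.csv(file.path(dir, "training_log.csv"))
  expect_identical(names(logged),
                   c("epoch", "step", "l_adv_ct", "l_adv_mr", "l_cycle",
                     "l_gc", "total"))
  ck <- load_checkpoint(file.path(dir, "checkpoint_last.rds"))
  expect_equal(ck$epoch, 2L)
  cfg4 <- tiny_config(epochs = 4)
  run2 <- fit(ds$a, ds$b, cfg4, resume_from = ck)
  expect_equal(sort(unique(run2$log$epoch)), 1:4)
  expect_equal(run2$nets$epoch, 4L)
  expect_error(fit(list(), ds$b, cfg), "at least one")
})

test_that("identical master seeds reproduce the loss trajectory exactly", {
  ds <- tiny_dataset()
  cfg <- tiny_config(seed = 123)
  r1 <- fit(ds$a, ds$b, cfg)
  r2 <- fit(ds$a, ds$b, cfg)
  expect_identical(r1$log, r2$log)
  r3 <- fit(ds$a, ds$b, tiny_config(seed = 124))
  expect_false(identical(r3$log$total, r1$log$total))
})

test_that("run_ablation trains four modes with matching directory layout", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  heldout <- make_phantom(phantom_spec(grid_shape = c(8, 8, 8), n_vertebrae = 2,
                                       seed = 77))
  cfg <- tiny_config(epochs = 1)
  res <- run_ablation(ds$a, ds$b, cfg, dir, heldout = list(heldout), T = 2)
  expect_true(all(dir.exists(file.path(dir, ablation_modes()))))
  expect_identical(nrow(res$comparison), 4L)
  for (mode in ablation_modes()) {
    fl <- ablation_flags(mode)
    persisted <- yaml::read_yaml(file.path(dir, mode, "config.yaml"))
    expect_equal(persisted$use_gc, fl$use_gc)
    expect_equal(persisted$use_uncertainty, fl$use_uncertainty)
    # only the switches differ between persisted configs
    rest <- persisted[setdiff(names(persisted), c("use_gc", "use_uncertainty"))]
    ref <- yaml::read_yaml(file.path(dir, ablation_modes()[1], "config.yaml"))
    expect_identical(rest, ref[names(rest)])
    alea <- file.path(dir, mode, "heldout01_aleatoric.nii.gz")
    expect_identical(file.exists(alea), fl$use_uncertainty)
  }
})
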