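# Full-grid runs here use a reduced censoring cap and frame rate so the
# whole suite stays fast; the censoring pattern is cap-invariant for the
# packaged scenarios whose endpoints fall below the reduced cap.
small_config <- function(seed = 1)
  toolbox_config(n_replicates = 2, seed = seed, fps = 2, cap_s = 30)

test_that("the full grid reproduces the cross-method censoring pattern", {
  out <- run_toolbox(small_config())
  expect_s3_class(out, "toolbox_summary")
  expect_equal(nrow(out$endpoints), 12)   # 4 films x 3 methods

  cell <- function(f, m)
    out$endpoints[out$endpoints$film == f & out$endpoints$method == m, ]
  # OCM: only P1 disintegrates; C1, C2, P2 censored
  expect_equal(cell("P1", "ocm")$n_censored, 0)
  expect_lt(abs(cell("P1", "ocm")$mean_s - 24.0), 2.0)
  for (f in c("C1", "C2", "P2")) {
    expect_equal(cell(f, "ocm")$n_observed, 0)
    expect_equal(cell(f, "ocm")$n_censored, 2)
    expect_match(cell(f, "ocm")$label, "^>30")
    expect_true(is.na(cell(f, "ocm")$mean_s))   # censored never averaged
  }
  # Petri: C2 censored, others observed near their scripted endpoints
  expect_equal(cell("C2", "petri")$n_observed, 0)
  expect_lt(abs(cell("C1", "petri")$mean_s - 25.3), 2.0)
  expect_lt(abs(cell("P1", "petri")$mean_s - 7.4), 2.0)
  expect_lt(abs(cell("P2", "petri")$mean_s - 22.2), 2.0)
  # BTM: friction endpoints below the reduced cap are observed; P1's
  # scripted 31 s endpoint falls beyond this run's 30 s cap and is
  # censored accordingly
  for (f in c("C1", "C2", "P2"))
    expect_equal(cell(f, "btm")$n_observed, 2)
  expect_equal(cell("P1", "btm")$n_censored, 2)

  # censored endpoints never reach the statistics blocks
  expect_false("C2" %in% names(out$stats$petri_endpoint$means))
  # mean CoF extremes: smallest for the highest-MW film (C2), largest
  # for a PVA film; P1 and P2 are deliberately near-equal so their
  # order is not asserted
  cof <- out$mean_cof
  expect_equal(cof$film[which.min(cof$mean_cof)], "C2")
  expect_true(cof$film[which.max(cof$mean_cof)] %in% c("P1", "P2"))
  mu <- function(f) cof$mean_cof[cof$film == f]
  expect_gt(mu("C1"), mu("C2"))
  expect_gt(mu("P1"), mu("C1"))
  expect_gt(mu("P2"), mu("C1"))
})

test_that("single-replicate cells flag the missing spread", {
  out <- run_toolbox(toolbox_config(films = "P1", methods = "petri",
                                    n_replicates = 1, seed = 2))
  expect_equal(nrow(out$endpoints), 1)
  expect_true(is.na(out$endpoints$sd_s))
  expect_match(out$endpoints$label, "n = 1")
})

test_that("reruns with identical config are byte-identical", {
  cfg <- toolbox_config(films = c("P1", "C2"),
                        methods = c("petri", "btm"),
                        n_replicates = 2, seed = 5)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_summary(run_toolbox(cfg), f1)
  write_summary(run_toolbox(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the output
  f3 <- tempfile(fileext = ".json")
  write_summary(run_toolbox(toolbox_config(films = c("P1", "C2"),
                                           methods = c("petri", "btm"),
                                           n_replicates = 2, seed = 6)),
                f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("profile plots are written and the plotted series is returned", {
  cfg <- toolbox_config(films = "P1", methods = "ocm", n_replicates = 3,
                        seed = 3, fps = 2, cap_s = 30)
  out <- run_toolbox(cfg)
  expect_length(out$profiles, 3)
  dir <- tempfile("plots")
  avg <- render_profiles(out$profiles, dir)
  expect_true(file.exists(file.path(dir, "profile_P1.png")))
  a <- avg$P1$area
  # the plotted mean series declines after the scripted detach as the
  # remnant shrinks and the detached fragment is carried away
  before <- a$mean[a$t_s < 23]
  late <- a$mean[a$t_s >= 28]
  expect_gt(min(before), 0.97)
  expect_lt(mean(late), 0.95)
  # constant profiles plot as a flat line at 1
  flat <- structure(data.frame(t_s = 0:10, area_px = 500,
                               area_fraction = 1, perimeter_px = 90,
                               n_fragments = 1,
                               largest_fragment_area_px = 500),
                    class = c("disintegration_profile", "data.frame"))
  avg2 <- render_profiles(list(F1.1 = flat, F1.2 = flat), tempfile())
  expect_equal(unique(avg2$F1$area$mean), 1)
  expect_error(render_profiles(list(), tempfile()), "empty")
})
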