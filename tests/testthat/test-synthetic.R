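test_that("default control coupling is hub-centric with PCC as pure sink", {
  spec <- make_default_coupling("control")
  nodes <- dmn_node_labels()
  hubs <- dmn_hub_labels()
  nonhubs <- setdiff(nodes, hubs)

  expect_identical(spec$node_labels, nodes)
  expect_identical(spec$hub_labels, hubs)

  # PCC receives from all 7 other nodes and sends nothing
  expect_setequal(spec$edges$source[spec$edges$target == "PCC"],
                  setdiff(nodes, "PCC"))
  expect_false("PCC" %in% spec$edges$source)

  # every hub/hub and hub/non-hub unordered pair carries a coupling;
  # non-hub pairs carry none
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  covered <- unique(pair_key(spec$edges$source, spec$edges$target))
  for (h in hubs) {
    for (other in setdiff(nodes, h)) {
      expected <- pair_key(h, other)
      expect_true(expected %in% covered, label = expected)
    }
  }
  for (a in nonhubs) for (b in setdiff(nonhubs, a))
    expect_false(pair_key(a, b) %in% covered)

  expect_lt(companion_spectral_radius(spec), 1)
})

test_that("attenuation scales exactly the non-PCC hub couplings", {
  ctrl <- make_default_coupling("control")
  same <- make_default_coupling("attenuated", attenuation_factor = 1)
  expect_equal(same$edges, ctrl$edges)

  gone <- make_default_coupling("attenuated", attenuation_factor = 0)
  # surviving edges are exactly the PCC afferents
  expect_setequal(unique(gone$edges$target), "PCC")
  expect_identical(nrow(gone$edges), 7L)

  half <- make_default_coupling("attenuated", attenuation_factor = 0.5)
  key <- function(e) paste(e$source, e$target, e$lag)
  m <- match(key(half$edges), key(ctrl$edges))
  senders <- c("MPFC", "lIPC", "rIPC")
  touched <- (half$edges$source %in% senders |
                half$edges$target %in% senders) &
    half$edges$target != "PCC"
  expect_equal(half$edges$coefficient[touched],
               0.5 * ctrl$edges$coefficient[m][touched])
  expect_equal(half$edges$coefficient[!touched],
               ctrl$edges$coefficient[m][!touched])

  expect_error(make_default_coupling("attenuated", attenuation_factor = 1.2),
               "\\[0, 1\\]")
})

test_that("simulate_subject matches the population Yule-Walker moments", {
  spec <- make_default_coupling("control")
  ts <- simulate_subject(spec, 30000, seed = 11)
  X <- ts$values
  T <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  emp_lag1 <- crossprod(Xc[-1, , drop = FALSE],
                        Xc[-T, , drop = FALSE]) / (T - 1)
  pop_lag1 <- oracle_lag_cov(spec, 1)
  scale <- max(abs(pop_lag1))
  expect_lt(max(abs(emp_lag1 - pop_lag1)), 0.05 * scale + 0.02)

  emp_var <- crossprod(Xc) / T
  pop_var <- oracle_lag_cov(spec, 0)
  expect_lt(max(abs(emp_var - pop_var)), 0.05 * max(abs(pop_var)) + 0.02)
})

test_that("null coupling gives independent white columns", {
  nodes <- dmn_node_labels()
  spec <- coupling_spec(nodes, dmn_hub_labels(),
                        data.frame(source = character(0),
                                   target = character(0),
                                   lag = integer(0),
                                   coefficient = numeric(0)),
                        matrix(0, 8, 5), order = 5)
  ts <- simulate_subject(spec, 20000, seed = 3)
  cc <- cor(ts$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  lag1 <- cor(ts$values[-1, ], ts$values[-20000, ])
  expect_lt(max(abs(lag1)), 0.05)
})

test_that("simulation is reproducible and rejects bad inputs", {
  spec <- make_default_coupling("control")
  a <- simulate_subject(spec, 295, seed = 5)
  b <- simulate_subject(spec, 295, seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_subject(spec, 295, seed = 6)$values))

  expect_error(simulate_subject(spec, 40, seed = 1), "10 x order")

  unstable <- spec
  unstable$self_coefficients[, 1] <- 1.05
  expect_error(simulate_subject(unstable, 295, seed = 1),
               "spectral radius")
  expect_error(
    coupling_spec(spec$node_labels, spec$hub_labels, spec$edges,
                  matrix(c(rep(1.05, 8), rep(0, 32)), 8, 5)),
    "spectral radius")
})

test_that("cohorts carry ground truth, honour the master seed, and jitter", {
  spec <- cohort_spec(make_default_coupling("control"), n_subjects = 4,
                      n_timepoints = 80, seed = 9,
                      between_subject_jitter = 0.1)
  co <- simulate_cohort(spec)
  expect_length(co$subjects, 4)
  expect_length(co$graphs, 4)
  for (g in co$graphs)
    expect_true(any(g$edges$source == "MPFC" & g$edges$target == "PCC"))

  co2 <- simulate_cohort(spec)
  for (i in 1:4)
    expect_identical(co$subjects[[i]]$values, co2$subjects[[i]]$values)

  # jitter varies coefficients across subjects but never flips signs
  c1 <- co$couplings[[1]]$edges$coefficient
  c2 <- co$couplings[[2]]$edges$coefficient
  expect_false(identical(c1, c2))
  expect_true(all(c1 >= 0) && all(c2 >= 0))

  single <- simulate_cohort(cohort_spec(make_default_coupling("control"),
                                        1, 80, seed = 2))
  expect_length(single$subjects, 1)
})

test_that("cohort round-trips through the TSV + JSON sidecar format", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_spec(make_default_coupling("control"),
                                    2, 80, seed = 4))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  back <- read_timeseries(file.path(dir, "subject01.tsv"))
  expect_equal(back$values, co$subjects[[1]]$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$node_labels, dmn_node_labels())
  side <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  expect_identical(side$n_subjects, 2L)
  expect_length(side$ground_truth_edges, 2)
})

test_that("optional HRF convolution preserves shape and is off by default", {
  spec <- make_default_coupling("control")
  plain <- simulate_subject(spec, 100, seed = 8)
  conv <- simulate_subject(spec, 100, seed = 8, hrf = TRUE)
  expect_identical(dim(conv$values), dim(plain$values))
  expect_false(identical(conv$values, plain$values))
  # smoothing: lag-1 autocorrelation increases under the HRF
  expect_gt(cor(conv$values[-1, 1], conv$values[-100, 1]),
            cor(plain$values[-1, 1], plain$values[-100, 1]))
})
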