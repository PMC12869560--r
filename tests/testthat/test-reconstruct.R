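recon_fixture <- function() memo("recon", function() {
  prep <- small_prepared()
  fit_reconstructor(prep$parts$train, prep$schema,
                    aggregation_map = prep$agg$map)
})

test_that("every reconstructed value lies inside its source band", {
  prep <- small_prepared()
  rec <- recon_fixture()
  tok <- prep$toks$test
  skel <- detokenize_structure(tok)
  syn <- reconstruct_cohort(tok, rec, rng_seed = 31)
  schema <- prep$schema
  # visit variables: align by patient/visit order
  syn_v <- dplyr::arrange(syn$visits, .data$patient_id, .data$visit_id)
  skel_v <- dplyr::arrange(skel$visits, .data$patient_id, .data$visit_id)
  for (f in c("los_total", "los_treatment")) {
    b <- skel_v[[paste0(f, "_band")]]
    v <- syn_v[[f]][match(paste(skel_v$patient_id, skel_v$visit_id),
                          paste(syn_v$patient_id, syn_v$visit_id))]
    expect_identical(is.na(v), is.na(b))   # missingness preserved
    ok <- !is.na(b)
    e <- schema$bands[[f]]
    expect_true(all(v[ok] >= e[b[ok]] & v[ok] <= e[b[ok] + 1]))
  }
  agev <- syn$patients$age
  ageb <- skel$patients$age_band
  ok <- !is.na(ageb)
  e <- schema$bands$age
  expect_true(all(agev[ok] >= e[ageb[ok]] & agev[ok] <= e[ageb[ok] + 1]))
})

test_that("two-stage KDE reconstruction beats uniform-in-band sampling", {
  set.seed(12)
  meanlog <- 3.5; sdlog <- 1
  train <- stats::rlnorm(8000, meanlog, sdlog)
  eval_v <- stats::rlnorm(8000, meanlog, sdlog)
  edges <- unique(stats::quantile(train, seq(0, 1, length.out = 11),
                                  names = FALSE))
  edges[1] <- 0; edges[length(edges)] <- max(edges) + 1
  g <- fit_marginal_kde(train, grid_resolution = 1, variable = "los")
  bl <- band_lookup(eval_v, edges)
  kde_rec <- sample_banded(bl$idx, edges, g)
  unif_rec <- stats::runif(length(eval_v), edges[bl$idx],
                           edges[bl$idx + 1])
  ks <- function(x) suppressWarnings(
    stats::ks.test(x, stats::plnorm, meanlog, sdlog)$statistic)
  expect_lt(ks(kde_rec), ks(unif_rec))
})

test_that("joint band reconstruction preserves the configured correlation", {
  cfg <- sim_config(seed = 13)
  set.seed(13)
  n <- 8000
  z1 <- stats::rnorm(n)
  z2 <- cfg$los_copula_rho * z1 + sqrt(1 - cfg$los_copula_rho^2) *
    stats::rnorm(n)
  x <- exp(cfg$los_meanlog[1] + cfg$los_sdlog[1] * z1)
  y <- exp(cfg$los_meanlog[2] + cfg$los_sdlog[2] * z2)
  ex <- unique(stats::quantile(x, seq(0, 1, length.out = 13), names = FALSE))
  ey <- unique(stats::quantile(y, seq(0, 1, length.out = 13), names = FALSE))
  ex[1] <- 0; ex[length(ex)] <- max(x) + 1
  ey[1] <- 0; ey[length(ey)] <- max(y) + 1
  j <- fit_joint_kde(x, y, grid_resolution_x = 2, grid_resolution_y = 2)
  bx <- band_lookup(x, ex)$idx
  by <- band_lookup(y, ey)$idx
  js <- sample_banded_joint(bx, by, ex, ey, j)
  r_joint <- stats::cor(js$x, js$y)
  expect_lt(abs(r_joint - 0.7), 0.1)
  # independent marginal reconstruction destroys the correlation
  gx <- fit_marginal_kde(x, grid_resolution = 2)
  gy <- fit_marginal_kde(y, grid_resolution = 2)
  xi <- sample_banded(bx, ex, gx)
  yi <- sample_banded(by, ey, gy)
  expect_lt(abs(stats::cor(xi, yi)), abs(r_joint - 0.2))
})

test_that("admission-mode reconstruction keeps exact tier-1 identities", {
  prep <- small_prepared()
  rec <- recon_fixture()
  syn <- reconstruct_cohort(prep$toks$test, rec, rng_seed = 41)
  los <- syn$visits$los_total
  short <- !is.na(los) & los <= 24
  delta <- as.numeric(difftime(syn$visits$end_time[short],
                               syn$visits$start_time[short],
                               units = "hours"))
  expect_equal(delta, los[short], tolerance = 1e-9)
  # visits stay chronologically ordered after repair
  byp <- split(syn$visits$start_time, syn$visits$patient_id)
  expect_true(all(vapply(byp, function(x) !is.unsorted(x), logical(1))))
})

test_that("weekly-mode gaps survive reconstruction exactly", {
  rec <- recon_fixture()
  set.seed(5)
  visits <- tibble::tibble(
    patient_id = rep(sprintf("p%03d", 1:200), each = 3),
    visit_seq = rep(1:3, 200),
    gap_weeks = as.integer(ifelse(rep(1:3, 200) == 1, NA,
                                  sample(0:8, 600, replace = TRUE))))
  out <- reconstruct_visit_dates(visits, rec$calendar)
  clamped_pat <- unique(out$patient_id[out$clamped])
  ok <- !out$patient_id %in% clamped_pat
  got <- unlist(tapply(out$week[ok], out$patient_id[ok], diff),
                use.names = FALSE)
  want <- out$gap_weeks[ok & out$visit_seq != 1]
  expect_identical(as.integer(got), want)
})

test_that("reconstructed cohorts mirror the three-table layout and expand codes", {
  prep <- small_prepared()
  rec <- recon_fixture()
  syn <- reconstruct_cohort(prep$toks$test, rec, rng_seed = 51)
  expect_s3_class(syn, "ehr_cohort")
  expect_true(all(c("patient_id", "gender", "age") %in%
                    names(syn$patients)))
  expect_true(all(c("patient_id", "visit_id", "start_time", "end_time",
                    "event_type", "los_total", "los_treatment") %in%
                    names(syn$visits)))
  # re-expanded codes are full-resolution members of the original vocabulary
  full_vocab <- sim_code_vocabulary(sim_config())
  expect_true(all(syn$diagnoses$code %in%
                    c(full_vocab, unique(prep$parts$train$diagnoses$code))))
  # round-trips through the sidecar file
  path <- withr::local_tempfile(fileext = ".rds")
  write_reconstructor(rec, path)
  back <- read_reconstructor(path)
  expect_equal(back$gap_grid$masses, rec$gap_grid$masses)
  expect_error(read_reconstructor(withr::local_tempfile(fileext = ".rds",
    lines = "")), "")
})
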