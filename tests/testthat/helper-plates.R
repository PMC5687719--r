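# Shared synthetic-plate fixtures. Expensive plates are built once per
# test run and cached; every builder is fully seeded so the suite is
# deterministic.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# n colonies on a jittered grid; per-colony parameters drawn once, seeded
grid_plate <- function(n, H, W, spacing, seed, Amax_rng = c(1500, 3000),
                       mu_max = 0.5, t0_rng = c(8, 12), KF_rng = c(8, 8),
                       F0 = 0.5, emission = c(0.25, 0.6, 0.15),
                       label = "strain", n_frames = 30,
                       frame_interval_h = 0.5, background = c(12, 9, 6),
                       noise_sigma = 2, jitter = 5) {
  set.seed(seed)
  grid <- expand.grid(r = seq(spacing / 2, H - spacing / 2, by = spacing),
                      c = seq(spacing / 2, W - spacing / 2, by = spacing))
  stopifnot(nrow(grid) >= n)
  grid <- grid[sample(nrow(grid), n), ]
  cols <- lapply(seq_len(n), function(i) colony_spec(
    c(grid$r[i] + runif(1, -jitter, jitter),
      grid$c[i] + runif(1, -jitter, jitter)),
    Amax = runif(1, Amax_rng[1], Amax_rng[2]), mu_max = mu_max,
    t0 = runif(1, t0_rng[1], t0_rng[2]),
    KF = runif(1, KF_rng[1], KF_rng[2]), F0 = F0, emission = emission,
    label = label))
  plate_spec(c(H, W), n_frames = n_frames,
             frame_interval_h = frame_interval_h, background = background,
             noise_sigma = noise_sigma, bit_depth = 8, seed = seed,
             colonies = cols)
}

# 12 well-separated colonies on a 512x512 plate (detection scenario)
detection_plate <- function() cached("detection", {
  spec <- grid_plate(12, 512, 512, spacing = 128, seed = 101)
  rp <- render_plate(spec)
  rp$stack <- subtract_background(rp$stack)
  rp
})

# 20 colonies on a 640x640 plate (growth / expression-rate scenario)
growth_plate <- function() cached("growth", {
  spec <- grid_plate(20, 640, 640, spacing = 128, seed = 202,
                     KF_rng = c(5, 12), n_frames = 48)
  rp <- render_plate(spec)
  rp$stack <- subtract_background(rp$stack)
  rp
})

# detection + per-colony growth fits for the growth plate
growth_plate_fits <- function() cached("growth_fits", {
  rp <- growth_plate()
  st <- rp$stack
  blobs <- detect_colonies(smooth_projection(temporal_sum_projection(st), 2))
  rois <- make_rois(blobs, 3, dim(st$frames)[2:3])
  fits <- lapply(seq_len(nrow(rois)), function(i)
    fit_growth_model(radius_series(st, rois[i, ])))
  list(rp = rp, blobs = blobs, rois = rois, fits = fits)
})

# strain emission vectors with G:R slopes 2.5 / 1.0 / 0.35
strain_emissions <- list(
  gfp   = c(0.25, 0.625, 0.125),
  ofp   = c(0.40, 0.400, 0.200),
  rfp   = c(0.60, 0.210, 0.190))

single_strain_plate <- function(strain, seed) {
  grid_plate(10, 512, 512, spacing = 96, seed = seed,
             Amax_rng = c(500, 900), t0_rng = c(7, 10), KF_rng = c(6, 10),
             emission = strain_emissions[[strain]], label = strain)
}

mixed_plate_spec <- function() {
  set.seed(304)
  grid <- expand.grid(r = seq(40, 600, by = 80), c = seq(40, 600, by = 80))
  grid <- grid[sample(nrow(grid), 30), ]
  labels <- rep(names(strain_emissions), each = 10)
  cols <- lapply(seq_len(30), function(i) colony_spec(
    c(grid$r[i] + runif(1, -5, 5), grid$c[i] + runif(1, -5, 5)),
    Amax = runif(1, 500, 900), mu_max = 0.5, t0 = runif(1, 7, 10),
    KF = runif(1, 6, 10), F0 = 0.5,
    emission = strain_emissions[[labels[i]]], label = labels[i]))
  plate_spec(c(640, 640), n_frames = 30, frame_interval_h = 0.5,
             background = c(12, 9, 6), noise_sigma = 2, bit_depth = 8,
             seed = 304, colonies = cols)
}

# full analysis of the classification plates: signatures from the three
# single-strain plates, totals for the mixed plate
classification_fixture <- function() cached("classification", {
  cfg <- analysis_config()
  plate_totals <- function(spec) {
    rp <- render_plate(spec)
    res <- analyze_plate(rp$stack, cfg)
    list(res = res, truth = rp$truth)
  }
  singles <- lapply(names(strain_emissions), function(s)
    plate_totals(single_strain_plate(s, seed = 300 + match(s, names(strain_emissions)))))
  names(singles) <- names(strain_emissions)
  sigs <- do.call(rbind, lapply(names(singles), function(s)
    fit_signature(singles[[s]]$res$totals, s)))
  mixed <- plate_totals(mixed_plate_spec())
  list(singles = singles, signatures = sigs, mixed = mixed)
})

# greedy one-to-one matching of detected blobs to ground-truth centers;
# returns per-truth-row distance to its matched blob (NA if unmatched)
match_blobs <- function(blobs, truth) {
  used <- rep(FALSE, nrow(blobs))
  err <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((blobs$row - truth$row[i])^2 + (blobs$col - truth$col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j])) { err[i] <- d[j]; used[j] <- TRUE }
  }
  err
}

# growth_fit built directly from known parameters (bypasses fitting)
fake_fit <- function(Amax, mu_max, t0, colony_id = 0L) {
  structure(list(colony_id = colony_id, Amax = Amax, mu_max = mu_max,
                 t0 = t0, residual_rms = 0, n_points_used = 99L,
                 convergence = TRUE),
            class = "growth_fit")
}
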