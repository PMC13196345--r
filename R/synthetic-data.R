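#' Moment-match the low mixture component from pooled statistics
#'
#' Published screen summaries often report the pooled mean/SD of all
#' normalized values together with the dominant (high-response) mixture
#' component; the low-response component is then fully determined by the
#' mixture moment identities
#' \deqn{\mu_{pool} = w \mu_h + (1-w) \mu_l}
#' \deqn{\sigma^2_{pool} + \mu^2_{pool} = w(\sigma_h^2 + \mu_h^2) + (1-w)(\sigma_l^2 + \mu_l^2)}
#'
#' @param mu_pool,sd_pool Pooled mean and SD of the full sample.
#' @param mu_high,sd_high Dominant-component mean and SD.
#' @param w_high Dominant-component weight (in (0, 1)).
#' @return List with `mu_low` and `sd_low`.
#' @export
match_low_component <- function(mu_pool = 0.687, sd_pool = 0.173,
                                mu_high = 0.734, sd_high = 0.085,
                                w_high = 0.91) {
  if (w_high <= 0 || w_high >= 1) {
    abort("w_high must be in (0, 1)", class = "mmpscreen_config_error")
  }
  w_low <- 1 - w_high
  mu_low <- (mu_pool - w_high * mu_high) / w_low
  var_low <- (sd_pool^2 + mu_pool^2 -
              w_high * (sd_high^2 + mu_high^2)) / w_low - mu_low^2
  if (var_low <= 0) {
    abort("pooled statistics incompatible with the high component",
          class = "mmpscreen_config_error")
  }
  list(mu_low = mu_low, sd_low = sqrt(var_low))
}

#' Draw from a two-component Gaussian mixture
#'
#' @param n Sample size.
#' @param means,sds,weights Component parameters (length 2; weights sum
#'   to 1).
#' @param seed Integer seed.
#' @return List with `values` and the true `component` (1 or 2) of each
#'   draw.
#' @export
sample_mmp_mixture <- function(n, means, sds, weights, seed = 1) {
  stopifnot(length(means) == 2, length(sds) == 2, length(weights) == 2)
  withr::with_seed(seed, {
    comp <- 1L + (runif(n) < weights[2])
    list(values = rnorm(n, means[comp], sds[comp]), component = comp)
  })
}

# mean-0, sample-SD-1 noise pattern: standardized Gaussian draws, so
# control-well sample statistics are exact by construction
std_pattern <- function(n) {
  x <- rnorm(n)
  (x - mean(x)) / sd(x)
}

#' Drug-screen generator configuration
#'
#' Defaults reproduce the statistical structure of a 1,134-compound
#' JC-10 MMP screen: background normalized ratios follow the
#' two-component Gaussian mixture (dominant component mean 0.734, SD
#' 0.085, weight 0.91; low component moment-matched to pooled 0.687 /
#' 0.173), rejected above `background_cap` so that planted rescuer counts
#' are exact; 20 planted rescuers uniform in [0.95, 1.20]; 88 treatments
#' per duplicated 96-well plate with 3 WT / 3 MT / 2 FCCP control wells;
#' per-plate Z' targets drawn inside the reported 0.09-0.51 band;
#' duplicate-well CVs drawn from a lognormal (median 7.6%, all below
#' 15%).
#'
#' @param n_compounds Number of treatments (default 1134).
#' @param mu_high,sigma_high,w_high Dominant-component parameters.
#' @param mu_low,sigma_low Low-component parameters; `NULL` (default)
#'   moment-matches them from `pooled_mean`/`pooled_sd`.
#' @param pooled_mean,pooled_sd Pooled statistics used for moment
#'   matching.
#' @param n_planted Number of planted rescuing compounds.
#' @param planted_range Normalized-ratio interval for planted rescuers.
#' @param background_cap Rejection bound for background draws (set to
#'   `Inf` to sample the pure mixture).
#' @param wt_raw_level,mt_raw_level,fccp_raw_level Raw F590/F520 control
#'   levels (arbitrary units).
#' @param z_prime_band Interval the per-plate Z' targets are drawn from.
#' @param cv_median,cv_sdlog,cv_cap Duplicate-CV lognormal parameters
#'   (percent) and hard cap.
#' @param f520_level,f520_sdlog Raw green-channel intensity model.
#' @param plate_scale_sdlog Lognormal SD of the per-plate intensity scale
#'   (removed by WT normalization).
#' @param seed Default seed for [gen_drug_screen()].
#' @return List of class `drug_screen_config`.
#' @export
drug_screen_config <- function(n_compounds = 1134,
                               mu_high = 0.734, sigma_high = 0.085,
                               w_high = 0.91,
                               mu_low = NULL, sigma_low = NULL,
                               pooled_mean = 0.687, pooled_sd = 0.173,
                               n_planted = 20,
                               planted_range = c(0.95, 1.20),
                               background_cap = 0.90,
                               wt_raw_level = 1.0, mt_raw_level = 0.69,
                               fccp_raw_level = 0.10,
                               z_prime_band = c(0.12, 0.48),
                               cv_median = 7.6, cv_sdlog = 0.30,
                               cv_cap = 14.5,
                               f520_level = 800, f520_sdlog = 0.08,
                               plate_scale_sdlog = 0.05,
                               seed = 1) {
  if (is.null(mu_low) || is.null(sigma_low)) {
    low <- match_low_component(pooled_mean, pooled_sd, mu_high, sigma_high,
                               w_high)
    mu_low <- low$mu_low
    sigma_low <- low$sd_low
  }
  cfg <- list(
    screen_type = "drug", n_treatments = n_compounds,
    mu_high = mu_high, sigma_high = sigma_high, w_high = w_high,
    mu_low = mu_low, sigma_low = sigma_low,
    n_planted = n_planted, planted_range = planted_range,
    background_cap = background_cap,
    wt_raw_level = wt_raw_level, mt_raw_level = mt_raw_level,
    fccp_raw_level = fccp_raw_level,
    z_prime_band = z_prime_band,
    cv_median = cv_median, cv_sdlog = cv_sdlog, cv_cap = cv_cap,
    f520_level = f520_level, f520_sdlog = f520_sdlog,
    plate_scale_sdlog = plate_scale_sdlog,
    treatments_per_plate = 88L, n_wt = 3L, n_mt = 3L, n_fccp = 2L,
    seed = seed
  )
  validate_screen_config(cfg)
  structure(cfg, class = c("drug_screen_config", "screen_config"))
}

#' siRNA-screen generator configuration
#'
#' Defaults emulate a 336-gene siRNA screen: background values
#' approximately Normal(0.710, 0.084) with a configurable right tail
#' (a `tail_fraction` of draws shifted up by `tail_shift`), rejected
#' above 0.87; 9 planted rescuers uniform in [0.95, 1.10]; 80 treatments
#' per duplicated plate with 4 WT / 4 MT control wells and no FCCP; Z'
#' targets inside the reported 0.302-0.370 band.
#'
#' @param n_genes Number of genes (default 336).
#' @param mu,sigma Background Normal parameters.
#' @param tail_fraction,tail_shift Right-tail model: fraction of
#'   background draws shifted up by `tail_shift` (normalized-ratio units).
#' @inheritParams drug_screen_config
#' @return List of class `sirna_screen_config`.
#' @export
sirna_screen_config <- function(n_genes = 336,
                                mu = 0.710, sigma = 0.084,
                                tail_fraction = 0.05, tail_shift = 0.10,
                                n_planted = 9,
                                planted_range = c(0.95, 1.10),
                                background_cap = 0.87,
                                wt_raw_level = 1.0, mt_raw_level = 0.71,
                                z_prime_band = c(0.305, 0.368),
                                cv_median = 7.6, cv_sdlog = 0.30,
                                cv_cap = 14.5,
                                f520_level = 800, f520_sdlog = 0.08,
                                plate_scale_sdlog = 0.05,
                                seed = 1) {
  cfg <- list(
    screen_type = "sirna", n_treatments = n_genes,
    mu = mu, sigma = sigma,
    tail_fraction = tail_fraction, tail_shift = tail_shift,
    n_planted = n_planted, planted_range = planted_range,
    background_cap = background_cap,
    wt_raw_level = wt_raw_level, mt_raw_level = mt_raw_level,
    fccp_raw_level = NA_real_,
    z_prime_band = z_prime_band,
    cv_median = cv_median, cv_sdlog = cv_sdlog, cv_cap = cv_cap,
    f520_level = f520_level, f520_sdlog = f520_sdlog,
    plate_scale_sdlog = plate_scale_sdlog,
    treatments_per_plate = 80L, n_wt = 4L, n_mt = 4L, n_fccp = 0L,
    seed = seed
  )
  validate_screen_config(cfg)
  structure(cfg, class = c("sirna_screen_config", "screen_config"))
}

validate_screen_config <- function(cfg) {
  if (cfg$n_planted > cfg$n_treatments) {
    abort("n_planted exceeds the number of treatments",
          class = "mmpscreen_config_error")
  }
  if (cfg$n_planted > 0 && cfg$planted_range[1] <= cfg$background_cap) {
    abort("planted_range must lie above background_cap",
          class = "mmpscreen_config_error")
  }
  invisible(cfg)
}

# rejection sampler: one background normalized value below the cap
draw_background <- function(n, cfg) {
  draw_one <- if (cfg$screen_type == "drug") {
    function(m) {
      comp <- 1L + (runif(m) >= cfg$w_high) # 1 = high, 2 = low
      mu <- c(cfg$mu_high, cfg$mu_low)[comp]
      sig <- c(cfg$sigma_high, cfg$sigma_low)[comp]
      list(v = rnorm(m, mu, sig),
           class = c("background_high", "background_low")[comp])
    }
  } else {
    function(m) {
      in_tail <- runif(m) < cfg$tail_fraction
      mu <- cfg$mu + ifelse(in_tail, cfg$tail_shift, 0)
      list(v = rnorm(m, mu, cfg$sigma),
           class = ifelse(in_tail, "background_tail", "background"))
    }
  }
  v <- numeric(0); cl <- character(0)
  while (length(v) < n) {
    d <- draw_one(max(n - length(v), 16L))
    keep <- d$v < cfg$background_cap & d$v > 0
    v <- c(v, d$v[keep]); cl <- c(cl, d$class[keep])
  }
  list(values = v[seq_len(n)], class = cl[seq_len(n)])
}

drug_control_wells <- function(cfg) {
  tibble(
    well = c("A12", "B12", "C12", "D12", "E12", "F12", "G12", "H12"),
    role = c(rep("wt_control", 3), rep("mt_control", 3),
             rep("fccp_control", 2))
  )
}

sirna_control_wells <- function(cfg) {
  tibble(
    well = paste0(LETTERS[1:8], 12),
    role = c(rep("wt_control", 4), rep("mt_control", 4))
  )
}

treatment_wells <- function(n) {
  idx <- seq_len(n) - 1L
  paste0(LETTERS[(idx %% 8L) + 1L], (idx %/% 8L) + 1L)
}

# build one physical plate: exact-by-construction control statistics
# (normalized WT mean 1, target Z') and treatment wells at the given
# normalized values
build_plate <- function(plate_id, cfg, treatment_ids, norm_values) {
  ctrl <- if (cfg$screen_type == "drug") drug_control_wells(cfg) else
    sirna_control_wells(cfg)
  mt_norm <- cfg$mt_raw_level / cfg$wt_raw_level
  window <- 1 - mt_norm
  z_target <- runif(1, cfg$z_prime_band[1], cfg$z_prime_band[2])
  sigma_sum <- (1 - z_target) * window / 3
  sigma_pos <- sigma_sum * 1 / (1 + mt_norm)
  sigma_neg <- sigma_sum * mt_norm / (1 + mt_norm)
  ctrl_norm <- numeric(nrow(ctrl))
  ctrl_norm[ctrl$role == "wt_control"] <- 1 + sigma_pos * std_pattern(cfg$n_wt)
  ctrl_norm[ctrl$role == "mt_control"] <-
    mt_norm + sigma_neg * std_pattern(cfg$n_mt)
  if (cfg$n_fccp > 0) {
    fccp_norm <- cfg$fccp_raw_level / cfg$wt_raw_level
    ctrl_norm[ctrl$role == "fccp_control"] <-
      fccp_norm + 0.01 * std_pattern(cfg$n_fccp)
  }
  plate_scale <- rlnorm(1, 0, cfg$plate_scale_sdlog)
  wells <- bind_rows(
    tibble(well = ctrl$well, role = ctrl$role,
           treatment_id = NA_character_, norm = ctrl_norm),
    tibble(well = treatment_wells(length(treatment_ids)),
           role = "treatment", treatment_id = treatment_ids,
           norm = norm_values)
  )
  ratio <- wells$norm * cfg$wt_raw_level * plate_scale
  f520 <- rlnorm(nrow(wells), log(cfg$f520_level), cfg$f520_sdlog)
  tibble(plate_id = plate_id, well = wells$well, role = wells$role,
         treatment_id = wells$treatment_id,
         f590 = ratio * f520, f520 = f520)
}

gen_screen <- function(cfg, seed) {
  withr::with_seed(seed, {
    n <- cfg$n_treatments
    ids <- sprintf("T%04d", seq_len(n))
    n_bg <- n - cfg$n_planted
    bg <- draw_background(n_bg, cfg)
    values <- c(runif(cfg$n_planted, cfg$planted_range[1],
                      cfg$planted_range[2]), bg$values)
    classes <- c(rep("planted_hit", cfg$n_planted), bg$class)
    ord <- sample.int(n) # spread planted hits across plates
    truth_tr <- tibble(treatment_id = ids, class = classes[ord],
                       true_value = values[ord])
    # duplicate-well dispersion: CV drawn per treatment, split as v(1 +/- d)
    cv <- rlnorm(n, log(cfg$cv_median), cfg$cv_sdlog)
    while (any(cv >= cfg$cv_cap)) {
      redo <- cv >= cfg$cv_cap
      cv[redo] <- rlnorm(sum(redo), log(cfg$cv_median), cfg$cv_sdlog)
    }
    delta <- cv / 100 / sqrt(2)
    sign_a <- sample(c(-1, 1), n, replace = TRUE)
    v <- truth_tr$true_value
    val_a <- v * (1 + sign_a * delta)
    val_b <- v * (1 - sign_a * delta)
    per_plate <- cfg$treatments_per_plate
    n_plates <- ceiling(n / per_plate)
    plates <- purrr::map_dfr(seq_len(n_plates), function(p) {
      sel <- ((p - 1) * per_plate + 1):min(p * per_plate, n)
      bind_rows(
        build_plate(sprintf("P%02d_A", p), cfg, ids[sel], val_a[sel]),
        build_plate(sprintf("P%02d_B", p), cfg, ids[sel], val_b[sel])
      )
    })
    ds <- screen_dataset(plates, cfg$screen_type)
    truth <- list(treatments = mutate(truth_tr, cv_percent = cv),
                  config = cfg, seed = seed)
    list(dataset = ds, truth = truth)
  })
}

#' Generate a synthetic drug screen with ground truth
#'
#' Background compounds draw their normalized ratio from the calibrated
#' two-component mixture (rejection-sampled below `background_cap` so the
#' planted-hit count is exact); planted rescuers are uniform in
#' `planted_range`. Each treatment appears on two duplicate plates whose
#' raw channel intensities are back-computed so that WT-referenced plate
#' normalization reproduces the target normalized values exactly up to
#' the drawn duplicate-well dispersion. Deterministic given `seed`.
#'
#' @param config A [drug_screen_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return List with `dataset` (a [screen_dataset()]) and `truth`
#'   (per-treatment effect class, true normalized value and duplicate CV,
#'   plus the config and seed).
#' @export
gen_drug_screen <- function(config = drug_screen_config(),
                            seed = config$seed) {
  stopifnot(inherits(config, "drug_screen_config"))
  gen_screen(config, seed)
}

#' Generate a synthetic siRNA screen with ground truth
#'
#' @param config A [sirna_screen_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return As [gen_drug_screen()].
#' @export
gen_sirna_screen <- function(config = sirna_screen_config(),
                             seed = config$seed) {
  stopifnot(inherits(config, "sirna_screen_config"))
  gen_screen(config, seed)
}

#' Generate a synthetic two-channel ratio image
#'
#' Disc-shaped cells of known per-cell F590/F520 ratio on a near-zero
#' background: the green channel carries a fixed intensity inside each
#' cell and the red channel is ratio * green, plus independent Gaussian
#' noise in both channels (SD = `noise_sigma` * `green_level`).
#'
#' @param n_cells Number of cells.
#' @param ratios Per-cell true ratios (recycled/drawn uniform in
#'   [0.5, 2.5] when `NULL`).
#' @param size Image side length in pixels.
#' @param noise_sigma Noise SD as a fraction of `green_level`.
#' @param seed Integer seed.
#' @param radius_range Cell radius interval in pixels.
#' @param green_level In-cell green intensity (a.u.).
#' @param background Background intensity in both channels (a.u.).
#' @return List with `image` (a [ratio_image()]) and `truth` (tibble:
#'   `cell`, `cx`, `cy`, `radius`, `ratio`).
#' @export
gen_ratio_image <- function(n_cells = 12, ratios = NULL, size = 256,
                            noise_sigma = 0.02, seed = 1,
                            radius_range = c(8, 14), green_level = 200,
                            background = 2) {
  withr::with_seed(seed, {
    if (is.null(ratios)) ratios <- runif(n_cells, 0.5, 2.5)
    ratios <- rep_len(ratios, n_cells)
    red <- matrix(background, size, size)
    green <- matrix(background, size, size)
    truth <- tibble(cell = integer(), cx = numeric(), cy = numeric(),
                    radius = numeric(), ratio = numeric())
    if (n_cells > 0) {
      placed <- matrix(numeric(0), ncol = 3) # cx, cy, r
      for (i in seq_len(n_cells)) {
        r <- runif(1, radius_range[1], radius_range[2])
        ok <- FALSE
        for (try in 1:2000) {
          cx <- runif(1, r + 2, size - r - 2)
          cy <- runif(1, r + 2, size - r - 2)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  placed[, 3] + r + 4)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort("could not place all cells: frame overcrowded",
                class = "mmpscreen_placement_error")
        }
        placed <- rbind(placed, c(cx, cy, r))
        truth <- bind_rows(truth, tibble(cell = i, cx = cx, cy = cy,
                                         radius = r, ratio = ratios[i]))
      }
      rows <- matrix(seq_len(size), size, size)
      cols <- matrix(seq_len(size), size, size, byrow = TRUE)
      for (i in seq_len(n_cells)) {
        px <- (rows - truth$cy[i])^2 + (cols - truth$cx[i])^2 <=
          truth$radius[i]^2
        green[px] <- green_level
        red[px] <- truth$ratio[i] * green_level
      }
    }
    if (noise_sigma > 0) {
      red <- pmax(red + rnorm(size^2, 0, noise_sigma * green_level), 0)
      green <- pmax(green + rnorm(size^2, 0, noise_sigma * green_level), 0)
    }
    list(image = ratio_image(red, green), truth = truth)
  })
}

#' Generate a binary mitochondrial mask of rasterized ellipses
#'
#' Non-touching ellipses with sampled aspect ratios and random
#' orientations; the ground truth records each object's true semi-axes.
#'
#' @param n_objects Number of objects.
#' @param ar_mean,ar_sd Aspect-ratio distribution (Normal truncated at 1);
#'   ignored when `ars` is given.
#' @param ars Optional explicit aspect ratios.
#' @param size Mask side length in pixels.
#' @param seed Integer seed.
#' @param minor_range Minor semi-axis interval in pixels.
#' @return List with `mask` (logical matrix) and `truth` (tibble: `object`,
#'   `cx`, `cy`, `semi_minor`, `semi_major`, `aspect_ratio`, `theta`).
#' @export
gen_mito_mask <- function(n_objects = 30, ar_mean = 2.5, ar_sd = 0.8,
                          ars = NULL, size = 256, seed = 1,
                          minor_range = c(2.5, 4.5)) {
  withr::with_seed(seed, {
    if (is.null(ars)) {
      ars <- pmax(rnorm(n_objects, ar_mean, ar_sd), 1)
    }
    ars <- rep_len(ars, n_objects)
    mask <- matrix(FALSE, size, size)
    truth <- tibble(object = integer(), cx = numeric(), cy = numeric(),
                    semi_minor = numeric(), semi_major = numeric(),
                    aspect_ratio = numeric(), theta = numeric())
    placed <- matrix(numeric(0), ncol = 3)
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (i in seq_len(n_objects)) {
      b <- runif(1, minor_range[1], minor_range[2])
      a <- ars[i] * b
      theta <- runif(1, 0, pi)
      ok <- FALSE
      for (try in 1:2000) {
        cx <- runif(1, a + 2, size - a - 2)
        cy <- runif(1, a + 2, size - a - 2)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + a + 3)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place all objects: mask overcrowded",
              class = "mmpscreen_placement_error")
      }
      placed <- rbind(placed, c(cx, cy, a))
      dx <- cols - cx
      dy <- rows - cy
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
      truth <- bind_rows(truth, tibble(
        object = i, cx = cx, cy = cy, semi_minor = b, semi_major = a,
        aspect_ratio = ars[i], theta = theta
      ))
    }
    list(mask = mask, truth = truth)
  })
}

#' Generate synthetic calcium fluorescence traces
#'
#' Each cell is oscillating with probability `p_oscillating`. Oscillating
#' cells receive a Poisson(rate * duration) number of transients at
#' uniform times thinned to a minimum spacing of `refractory_s` seconds
#' (overlapping transients are not resolvable at the 2 s frame interval);
#' each transient has a double-exponential shape (rise `tau_rise_s`,
#' decay `tau_decay_s`) with peak F/F0 drawn from a truncated Normal.
#' Non-oscillating cells carry baseline noise only.
#'
#' @param n_cells Number of cells.
#' @param p_oscillating Per-cell oscillation probability.
#' @param rate_per_min Transient rate in events per minute.
#' @param amplitude_mean,amplitude_sd Peak F/F0 distribution of planted
#'   transients (Normal truncated at `amplitude_floor`).
#' @param duration_s Recording length in seconds.
#' @param dt_s Frame interval in seconds (default 2).
#' @param noise_sigma Noise SD as a fraction of baseline.
#' @param baseline Baseline fluorescence (a.u.).
#' @param seed Integer seed.
#' @param refractory_s Minimum spacing between planted transients.
#' @param tau_rise_s,tau_decay_s Transient shape time constants.
#' @param amplitude_floor Lower truncation of peak F/F0 (> 1).
#' @return List with `traces` (list of [fluorescence_trace()]) and
#'   `truth` (tibble: `cell_id`, `oscillating`, `n_events`, plus nested
#'   `event_times` and `amplitudes`).
#' @export
gen_calcium_traces <- function(n_cells, p_oscillating, rate_per_min,
                               amplitude_mean, amplitude_sd = 0.35,
                               duration_s = 300, dt_s = 2,
                               noise_sigma = 0.015, baseline = 100,
                               seed = 1, refractory_s = 12,
                               tau_rise_s = 1, tau_decay_s = 6,
                               amplitude_floor = 1.2) {
  if (dt_s <= 0) abort("dt_s must be > 0", class = "mmpscreen_config_error")
  if (rate_per_min < 0 || duration_s <= 0) {
    abort("rate and duration must be non-negative",
          class = "mmpscreen_config_error")
  }
  t_frames <- seq(0, duration_s, by = dt_s)
  t_peak <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  shape_norm <- exp(-t_peak / tau_decay_s) - exp(-t_peak / tau_rise_s)
  withr::with_seed(seed, {
    osc <- runif(n_cells) < p_oscillating
    traces <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    t_lo <- 5
    t_hi <- duration_s - 3 * tau_decay_s
    for (i in seq_len(n_cells)) {
      times <- numeric(0)
      amps <- numeric(0)
      if (osc[i]) {
        n_ev <- rpois(1, rate_per_min * duration_s / 60)
        n_ev <- min(n_ev, floor((t_hi - t_lo) / refractory_s) + 1)
        if (n_ev > 0) {
          tries <- 0
          repeat {
            times <- sort(runif(n_ev, t_lo, t_hi))
            if (n_ev == 1 || all(diff(times) >= refractory_s)) break
            tries <- tries + 1
            if (tries %% 1000 == 0) n_ev <- n_ev - 1 # thin infeasible draws
          }
          amps <- rnorm(n_ev, amplitude_mean, amplitude_sd)
          while (any(amps < amplitude_floor)) {
            redo <- amps < amplitude_floor
            amps[redo] <- rnorm(sum(redo), amplitude_mean, amplitude_sd)
          }
        }
      }
      f <- rep(1, length(t_frames))
      for (k in seq_along(times)) {
        dtk <- t_frames - times[k]
        s <- ifelse(dtk >= 0,
                    (exp(-dtk / tau_decay_s) - exp(-dtk / tau_rise_s)) /
                      shape_norm, 0)
        f <- f + (amps[k] - 1) * s
      }
      values <- baseline * f + baseline * noise_sigma *
        rnorm(length(t_frames))
      values <- pmax(values, baseline * 1e-3)
      traces[[i]] <- fluorescence_trace(sprintf("cell%04d", i), values,
                                        dt = dt_s)
      truth[[i]] <- tibble(cell_id = sprintf("cell%04d", i),
                           oscillating = osc[i], n_events = length(times),
                           event_times = list(times),
                           amplitudes = list(amps))
    }
    list(traces = traces, truth = bind_rows(truth))
  })
}

#' Generate a random binary-branching neuron tree
#'
#' A soma at the origin sends out a single trunk; every subsequent node
#' up to `depth` segment levels branches into two children with
#' probability `branching_prob` (one child otherwise). Segment lengths
#' are Normal(`segment_length_mean`, `segment_length_sd`) truncated at
#' 1 um, directions uniform on the sphere. The ground truth records the
#' exact total length and terminal count from the construction.
#'
#' @param depth Number of segment levels (>= 1).
#' @param segment_length_mean,segment_length_sd Segment length
#'   distribution (micrometres).
#' @param branching_prob Probability a node spawns two children.
#' @param seed Integer seed.
#' @return List with `tree` (a [neuron_tree()]) and `truth`
#'   (`total_length`, `n_terminals`).
#' @export
gen_neuron_tree <- function(depth = 4, segment_length_mean = 40,
                            segment_length_sd = 8, branching_prob = 0.6,
                            seed = 1) {
  if (depth < 1) abort("depth must be >= 1", class = "mmpscreen_config_error")
  withr::with_seed(seed, {
    nodes <- tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                    radius = 2, parent = -1L)
    total <- 0
    next_id <- 2L
    grow <- function(parent_id, parent_xyz, level) {
      n_children <- if (level == 1) 1L else
        if (runif(1) < branching_prob) 2L else 1L
      for (ch in seq_len(n_children)) {
        len <- max(rnorm(1, segment_length_mean, segment_length_sd), 1)
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        xyz <- parent_xyz + len * dir
        id <- next_id
        next_id <<- next_id + 1L
        nodes <<- bind_rows(nodes, tibble(
          id = id, type = 3L, x = xyz[1], y = xyz[2], z = xyz[3],
          radius = 0.5, parent = parent_id
        ))
        total <<- total + len
        if (level < depth) grow(id, xyz, level + 1)
      }
    }
    grow(1L, c(0, 0, 0), 1)
    tree <- neuron_tree(nodes)
    list(tree = tree,
         truth = list(total_length = total,
                      n_terminals = terminal_points(tree)))
  })
}
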