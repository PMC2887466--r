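#' Configuration of the synthetic screen generator
#'
#' The generator emulates a genome-wide, duplicate, two-condition cytoblot
#' RNAi screen on 384-well plates stamped from four 96-well source plates.
#' Per-well cell number (`nucfl`) is log-normal; the phospho-signal
#' follows, on the log2 scale,
#' `log2(pdakt) = gain + beta * log2(nucfl) + S * [insulin] + pos(row, col)
#'  + tau_cond * q(plate, quadrant, replicate) + delta(amplicon, condition)
#'  + eps`, with `eps ~ Normal(0, sigma(n))` and
#' `sigma(n) = sigma0 + sigma1 / sqrt(n / median n)` (noisier at low cell
#' counts). `pos` is a deterministic edge depression, `q` a per-
#' (plate, quadrant, replicate) source-plate batch offset applied with
#' condition-specific amplitude (`tau_baseline` by default, zero for the
#' insulin condition, mirroring that only the unstimulated screen showed
#' strong source-plate variation). Planted suppressors act in the insulin
#' condition, planted enhancers in the baseline condition; the two known-
#' component panels carry graded per-member effects. All randomness flows
#' from one seeded stream in a fixed draw order whose draw counts do not
#' depend on amplitude parameters, so e.g. a `tau_baseline` sweep reuses
#' bit-identical noise.
#'
#' @param n_plates number of library plates (default 58).
#' @param n_replicates screen replicates per condition (default 2).
#' @param conditions conditions to emit (default both).
#' @param nucfl_median,nucfl_sdlog log-normal law of the cell-number proxy
#'   (arbitrary units; defaults 1e4 and 0.6 -- RNAi knockdowns change cell
#'   numbers severalfold).
#' @param gain_log2 log2 detection gain of the phospho-signal (default 10).
#' @param beta slope of log2 signal versus log2 cell number (default 0.9,
#'   slightly sub-proportional: dense wells saturate).
#' @param insulin_shift log2 signal increase under insulin (default 2).
#' @param sigma0,sigma1 noise-model parameters, log2 units (defaults 0.14,
#'   0.06).
#' @param edge_amp log2 signal depression of edge wells (default 0.15).
#' @param tau_baseline,tau_insulin SD of the per-(plate, quadrant,
#'   replicate) batch offset, log2 units (defaults 0.3 and 0).
#' @param n_suppressors,n_enhancers planted hit counts (defaults 200 each).
#' @param suppressor_delta,enhancer_delta planted log2 effect sizes;
#'   `NULL` (default) uses [planted_delta()] at `hit_strength_sd`
#'   pipeline SDs (pooled residual SDs for insulin suppressors,
#'   within-plate baseline SDs for baseline enhancers).
#' @param hit_strength_sd strength of default planted effects in pipeline
#'   SDs (default 3, a moderate knockdown); the effect is self-consistent
#'   in that the pipeline SD includes the planted hits' own variance
#'   contribution.
#' @param panel_upstream_mult,panel_tsc_tor_mult per-member effect sizes
#'   of the known-component panels, in multiples of the respective
#'   pipeline SD; lengths set the panel sizes (defaults: 8 members acting
#'   as insulin suppressors, 11 as baseline enhancers, graded so recovery
#'   is partial -- illustrative defaults, not estimates of real effects).
#' @param off_target_fraction fraction of null amplicons flagged as
#'   predicted off-target (default 0.05; planted hits and panel members
#'   are never flagged, so recovery measures the pipeline, not annotation
#'   attrition).
#' @param seed integer seed.
#' @return validated list of class `screen_config`.
#' @export
screen_config <- function(n_plates = 58, n_replicates = 2,
                          conditions = c("baseline", "insulin"),
                          nucfl_median = 1e4, nucfl_sdlog = 0.6,
                          gain_log2 = 10, beta = 0.9, insulin_shift = 2,
                          sigma0 = 0.10, sigma1 = 0.10,
                          edge_amp = 0.15,
                          tau_baseline = 0.3, tau_insulin = 0,
                          n_suppressors = 200, suppressor_delta = NULL,
                          n_enhancers = 200, enhancer_delta = NULL,
                          hit_strength_sd = 3,
                          panel_upstream_mult = c(-6, -5.5, -5, -4.5, -4,
                                                  -2, -1.6, -1.2),
                          panel_tsc_tor_mult = c(6, 5.5, 5, 5, 4.5, 4.5,
                                                 4, 4, 4, 4, 1.2),
                          off_target_fraction = 0.05,
                          seed = 1) {
  cfg <- list(n_plates = as.integer(n_plates),
              n_replicates = as.integer(n_replicates),
              conditions = match.arg(conditions, .conditions, several.ok = TRUE),
              nucfl_median = nucfl_median, nucfl_sdlog = nucfl_sdlog,
              gain_log2 = gain_log2, beta = beta,
              insulin_shift = insulin_shift,
              sigma0 = sigma0, sigma1 = sigma1, edge_amp = edge_amp,
              tau_baseline = tau_baseline, tau_insulin = tau_insulin,
              n_suppressors = as.integer(n_suppressors),
              suppressor_delta = suppressor_delta,
              n_enhancers = as.integer(n_enhancers),
              enhancer_delta = enhancer_delta,
              panel_upstream_mult = panel_upstream_mult,
              panel_tsc_tor_mult = panel_tsc_tor_mult,
              off_target_fraction = off_target_fraction,
              hit_strength_sd = hit_strength_sd,
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "screen_config"
  if (is.null(cfg$suppressor_delta)) {
    cfg$suppressor_delta <- -planted_delta(cfg, hit_strength_sd, "insulin")
  }
  if (is.null(cfg$enhancer_delta)) {
    cfg$enhancer_delta <- +planted_delta(cfg, hit_strength_sd, "baseline")
  }
  cfg
}

#' Self-consistent planted effect size at a stated SD multiple
#'
#' The log2 effect `delta` such that planting `n_hits` hits of that size
#' makes `delta` equal `n_sd` times the pipeline's pooled dispersion
#' *including the planted hits' own variance contribution*: `delta`
#' solves `delta^2 = n_sd^2 (v0 + (n_hits / n_amp) delta^2)`, where `v0`
#' is the no-hit pooled variance the pipeline sees
#' ([insulin_pooled_sd()]^2 or [baseline_plate_sd()]^2).
#'
#' @param config a [screen_config()].
#' @param n_sd effect size in realized pipeline SDs.
#' @param pipeline `"insulin"` (pooled-residual scale) or `"baseline"`
#'   (within-plate scale).
#' @return positive log2 effect size.
#' @export
planted_delta <- function(config, n_sd, pipeline = c("insulin", "baseline")) {
  pipeline <- match.arg(pipeline)
  n_amp <- config$n_plates * 384
  if (pipeline == "insulin") {
    .self_consistent_delta(insulin_pooled_sd(config)^2,
                           config$n_suppressors / n_amp, n_sd)
  } else {
    .self_consistent_delta(baseline_plate_sd(config)^2,
                           config$n_enhancers / n_amp, n_sd)
  }
}

.validate_config <- function(cfg) {
  stopifnot(cfg$n_plates >= 1, cfg$n_replicates >= 1)
  for (nm in c("nucfl_median", "nucfl_sdlog", "sigma0", "sigma1",
               "edge_amp", "tau_baseline", "tau_insulin")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0) {
      stop("config field '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$off_target_fraction < 0 || cfg$off_target_fraction > 1) {
    stop("config field 'off_target_fraction' must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(cfg$hit_strength_sd) || cfg$hit_strength_sd <= 0) {
    stop("config field 'hit_strength_sd' must be a positive number",
         call. = FALSE)
  }
  n_amp <- cfg$n_plates * 384L
  n_groups <- cfg$n_plates * 4L
  if (cfg$n_suppressors > n_groups || cfg$n_enhancers > n_groups) {
    stop("planted hit counts exceed the number of source-plate groups (",
         n_groups, "); hits are placed at most one per group", call. = FALSE)
  }
  n_special <- cfg$n_suppressors + cfg$n_enhancers +
    length(cfg$panel_upstream_mult) + length(cfg$panel_tsc_tor_mult)
  if (n_special + round(cfg$off_target_fraction * n_amp) > n_amp) {
    stop("planted hits, panels and off-target flags exceed the library size",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Closed-form noise scales implied by a generator configuration
#'
#' `pooled_noise_sd()` is the log2-scale SD of the pooled per-well noise,
#' `sqrt(E[sigma(n)^2])` under the log-normal cell-number law (lognormal
#' moments `E[u^a] = exp(a^2 sdlog^2 / 2)` for `u = n / median`).
#' `insulin_pooled_sd()` adds the edge-term variance that survives the
#' per-plate regression and so shows up in the pooled residuals.
#' `baseline_plate_sd()` adds the deterministic within-plate variance
#' sources seen by the baseline pipeline on the log2 scale: the cell-
#' number trend through `beta` and the edge-well depression.
#'
#' @param config a [screen_config()].
#' @return a single number (log2 units).
#' @export
pooled_noise_sd <- function(config) {
  s0 <- config$sigma0; s1 <- config$sigma1; sl <- config$nucfl_sdlog
  sqrt(s0^2 + 2 * s0 * s1 * exp(sl^2 / 8) + s1^2 * exp(sl^2 / 2))
}

#' @rdname pooled_noise_sd
#' @export
insulin_pooled_sd <- function(config) {
  f_edge <- 76 / 384
  sqrt(pooled_noise_sd(config)^2 +
         f_edge * (1 - f_edge) * config$edge_amp^2)
}

# delta with delta^2 = n_sd^2 (v0 + frac delta^2)
.self_consistent_delta <- function(v0, frac, n_sd) {
  shrink <- 1 - n_sd^2 * frac
  if (shrink <= 0) {
    stop("planted-hit fraction too large for a self-consistent ", n_sd,
         "-SD effect size", call. = FALSE)
  }
  n_sd * sqrt(v0 / shrink)
}

#' @rdname pooled_noise_sd
#' @export
baseline_plate_sd <- function(config) {
  f_edge <- 76 / 384  # fraction of edge wells on a 16 x 24 plate
  sqrt((config$beta - 1)^2 * (config$nucfl_sdlog / log(2))^2 +
         f_edge * (1 - f_edge) * config$edge_amp^2 +
         pooled_noise_sd(config)^2)
}

#' A null-screen configuration for calibration runs
#'
#' Zero planted effects and zero systematic artifacts (edge and quadrant
#' terms off), heteroscedastic measurement noise retained: raw Z-scores
#' are then a pure probe of the error model's calibration.
#'
#' @param seed integer seed.
#' @param ... further arguments to [screen_config()].
#' @export
null_screen_config <- function(seed = 1, ...) {
  screen_config(n_suppressors = 0, n_enhancers = 0,
                panel_upstream_mult = numeric(0),
                panel_tsc_tor_mult = numeric(0),
                off_target_fraction = 0, edge_amp = 0,
                tau_baseline = 0, tau_insulin = 0, seed = seed, ...)
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "screen_config: %d plates x 384 wells x %d replicates, conditions: %s\n",
    x$n_plates, x$n_replicates, paste(x$conditions, collapse = ", ")))
  cat(sprintf("  noise: sigma(n) = %.3g + %.3g/sqrt(n/median); pooled SD %.4g\n",
              x$sigma0, x$sigma1, pooled_noise_sd(x)))
  cat(sprintf("  planted: %d suppressors (delta %.3g), %d enhancers (delta %.3g)\n",
              x$n_suppressors, x$suppressor_delta,
              x$n_enhancers, x$enhancer_delta))
  invisible(x)
}

# deterministic per-well edge depression (log2 units)
.edge_term <- function(row, col, edge_amp) {
  -edge_amp * as.numeric(row == 1 | row == 16 | col == 1 | col == 24)
}

#' Simulate a genome-wide screen with ground truth
#'
#' Emits a full measurement dataset (library plates for every condition
#' and replicate, plus two dedicated 384-well untreated standard plates
#' per condition, i.e. 768 standard wells spanning the density spectrum),
#' together with the ground truth of every planted effect and an amplicon
#' annotation table. Byte-identical output for a fixed config and seed.
#'
#' @param config a [screen_config()].
#' @return list with `dataset` (a [screen_dataset]), `truth` (per-amplicon
#'   class, per-condition log2 effect, off-target flag), `annotation`
#'   (amplicon, gene, known-component class), and `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_amp <- cfg$n_plates * 384L
  amp_ids <- sprintf("AMP%05d", seq_len(n_amp))
  addr <- plate_addresses()

  # --- ground truth assignment ---
  # Planted suppressors and enhancers are placed spike-in style, at most
  # one per (plate, source-plate quadrant) group, so planted effects do
  # not confound each other inside the 96-well groups whose statistics
  # the pipelines estimate; panels and off-target flags are uniform.
  group_of <- rep((seq_len(cfg$n_plates) - 1L) * 4L, each = 384L) +
    rep(addr$quadrant, cfg$n_plates)
  members <- split(seq_len(n_amp), group_of)
  n_groups <- length(members)
  place_spikes <- function(n, taken) {
    if (n == 0) return(integer(0))
    gs <- sample.int(n_groups, n)
    vapply(gs, function(g) {
      free <- setdiff(members[[g]], taken)
      free[sample.int(length(free), 1L)]
    }, integer(1))
  }
  idx_sup <- place_spikes(cfg$n_suppressors, integer(0))
  idx_enh <- place_spikes(cfg$n_enhancers, idx_sup)
  n_up <- length(cfg$panel_upstream_mult)
  n_tt <- length(cfg$panel_tsc_tor_mult)
  n_ot <- as.integer(round(cfg$off_target_fraction * n_amp))
  pool <- setdiff(sample.int(n_amp), c(idx_sup, idx_enh))
  idx_up <- if (n_up > 0) pool[seq_len(n_up)] else integer(0)
  idx_tt <- if (n_tt > 0) pool[n_up + seq_len(n_tt)] else integer(0)
  idx_ot <- if (n_ot > 0) pool[n_up + n_tt + seq_len(n_ot)] else integer(0)

  class_vec <- rep("null", n_amp)
  class_vec[idx_sup] <- "suppressor"
  class_vec[idx_enh] <- "enhancer"
  class_vec[idx_up] <- "panel_upstream"
  class_vec[idx_tt] <- "panel_tsc_tor"
  delta_ins <- numeric(n_amp)
  delta_base <- numeric(n_amp)
  delta_ins[idx_sup] <- cfg$suppressor_delta
  delta_base[idx_enh] <- cfg$enhancer_delta
  delta_ins[idx_up] <- cfg$panel_upstream_mult * pooled_noise_sd(cfg)
  delta_base[idx_tt] <- cfg$panel_tsc_tor_mult * baseline_plate_sd(cfg)
  off_target <- rep(FALSE, n_amp)
  off_target[idx_ot] <- TRUE

  truth <- data.frame(amplicon_id = amp_ids, class = class_vec,
                      delta_baseline = delta_base, delta_insulin = delta_ins,
                      off_target = off_target, stringsAsFactors = FALSE)
  annotation <- data.frame(
    amplicon_id = amp_ids,
    gene_id = sprintf("GENE%05d", seq_len(n_amp)),
    known_component_class = ifelse(class_vec == "panel_upstream",
                                   "upstream_InR_branch",
                                   ifelse(class_vec == "panel_tsc_tor",
                                          "tsc_tor_branch", "none")),
    off_target = off_target, stringsAsFactors = FALSE)

  # --- library plates (fixed draw order: nucfl, quadrant offsets, eps) ---
  n_wells <- cfg$n_plates * 384L
  plate_of <- rep(seq_len(cfg$n_plates), each = 384L)
  edge <- rep(.edge_term(addr$row, addr$col, cfg$edge_amp), cfg$n_plates)
  quad <- rep(addr$quadrant, cfg$n_plates)
  parts <- vector("list", length(cfg$conditions) * cfg$n_replicates)
  pi_ <- 0L
  for (cond in c("baseline", "insulin")) {
    if (!(cond %in% cfg$conditions)) next
    tau <- if (cond == "baseline") cfg$tau_baseline else cfg$tau_insulin
    shift <- if (cond == "insulin") cfg$insulin_shift else 0
    delta <- if (cond == "insulin") delta_ins else delta_base
    for (rep_i in seq_len(cfg$n_replicates)) {
      nucfl <- stats::rlnorm(n_wells, log(cfg$nucfl_median), cfg$nucfl_sdlog)
      q_raw <- stats::rnorm(cfg$n_plates * 4L)
      eps_raw <- stats::rnorm(n_wells)
      sigma <- cfg$sigma0 + cfg$sigma1 / sqrt(nucfl / cfg$nucfl_median)
      q_term <- tau * q_raw[(plate_of - 1L) * 4L + quad]
      log2pd <- cfg$gain_log2 + cfg$beta * log2(nucfl) + shift + edge +
        q_term + delta + eps_raw * sigma
      pi_ <- pi_ + 1L
      parts[[pi_]] <- data.frame(
        plate = sprintf("P%02d", plate_of),
        replicate = rep_i, condition = cond,
        well = rep(addr$well, cfg$n_plates),
        amplicon_id = amp_ids,
        control_class = "sample",
        off_target = off_target,
        pdakt = 2^log2pd, nucfl = nucfl,
        stringsAsFactors = FALSE)
    }
  }

  # --- dedicated untreated standard plates: 768 wells per condition,
  #     density spectrum covered by a deterministic quantile grid ---
  n_std <- 768L
  std_nucfl_grid <- stats::qlnorm((seq_len(n_std) - 0.5) / n_std,
                                  log(cfg$nucfl_median), cfg$nucfl_sdlog)
  for (cond in c("baseline", "insulin")) {
    if (!(cond %in% cfg$conditions)) next
    shift <- if (cond == "insulin") cfg$insulin_shift else 0
    eps_raw <- stats::rnorm(n_std)
    nucfl <- std_nucfl_grid
    sigma <- cfg$sigma0 + cfg$sigma1 / sqrt(nucfl / cfg$nucfl_median)
    log2pd <- cfg$gain_log2 + cfg$beta * log2(nucfl) + shift + eps_raw * sigma
    pi_ <- pi_ + 1L
    parts[[pi_]] <- data.frame(
      plate = rep(c("STD1", "STD2"), each = 384L),
      replicate = 1L, condition = cond,
      well = rep(addr$well, 2L),
      amplicon_id = "CTRL_UNTREATED",
      control_class = "untreated",
      off_target = FALSE,
      pdakt = 2^log2pd, nucfl = nucfl,
      stringsAsFactors = FALSE)
  }

  df <- do.call(rbind, parts[seq_len(pi_)])
  list(dataset = screen_dataset(df), truth = truth, annotation = annotation,
       config = cfg)
}

#' Simulate a follow-up experiment for the external-standard workflow
#'
#' Emits, per condition, 768 untreated standard wells spanning the density
#' spectrum plus `n_replicates` treated wells for each declared treatment,
#' with per-condition log2 effects.
#'
#' @param config a [screen_config()] (noise model and conditions reused).
#' @param treatments data.frame with columns `treatment`,
#'   `delta_baseline`, `delta_insulin` (log2 effects).
#' @param n_replicates treated replicate wells per treatment and condition
#'   (default 7).
#' @param seed integer seed (defaults to the config's).
#' @return list with `dataset` (a [screen_dataset]) and `config`.
#' @export
simulate_followup <- function(config, treatments, n_replicates = 7,
                              seed = config$seed) {
  stopifnot(inherits(config, "screen_config"),
            all(c("treatment", "delta_baseline", "delta_insulin") %in%
                  names(treatments)))
  cfg <- config
  set.seed(as.integer(seed))
  n_std <- 768L
  addr <- plate_addresses()
  std_nucfl <- stats::qlnorm((seq_len(n_std) - 0.5) / n_std,
                             log(cfg$nucfl_median), cfg$nucfl_sdlog)
  n_trt <- nrow(treatments) * n_replicates
  parts <- list()
  for (cond in c("baseline", "insulin")) {
    if (!(cond %in% cfg$conditions)) next
    shift <- if (cond == "insulin") cfg$insulin_shift else 0
    eps_std <- stats::rnorm(n_std)
    sig_std <- cfg$sigma0 + cfg$sigma1 / sqrt(std_nucfl / cfg$nucfl_median)
    parts[[length(parts) + 1L]] <- data.frame(
      plate = rep(c("STD1", "STD2"), each = 384L),
      replicate = 1L, condition = cond, well = rep(addr$well, 2L),
      amplicon_id = "CTRL_UNTREATED", control_class = "untreated",
      off_target = FALSE,
      pdakt = 2^(cfg$gain_log2 + cfg$beta * log2(std_nucfl) + shift +
                   eps_std * sig_std),
      nucfl = std_nucfl, stringsAsFactors = FALSE)
    nucfl_t <- stats::rlnorm(n_trt, log(cfg$nucfl_median), cfg$nucfl_sdlog)
    eps_t <- stats::rnorm(n_trt)
    sig_t <- cfg$sigma0 + cfg$sigma1 / sqrt(nucfl_t / cfg$nucfl_median)
    delta <- rep(if (cond == "insulin") treatments$delta_insulin else
      treatments$delta_baseline, each = n_replicates)
    parts[[length(parts) + 1L]] <- data.frame(
      plate = sprintf("FUP%d", (seq_len(n_trt) - 1L) %/% 384L + 1L),
      replicate = rep(seq_len(n_replicates), times = nrow(treatments)),
      condition = cond,
      well = addr$well[(seq_len(n_trt) - 1L) %% 384L + 1L],
      amplicon_id = rep(treatments$treatment, each = n_replicates),
      control_class = "sample", off_target = FALSE,
      pdakt = 2^(cfg$gain_log2 + cfg$beta * log2(nucfl_t) + shift + delta +
                   eps_t * sig_t),
      nucfl = nucfl_t, stringsAsFactors = FALSE)
  }
  list(dataset = screen_dataset(do.call(rbind, parts)), config = cfg)
}
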