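#' SART presets
#'
#' Two standard task layouts: `"exp1"` with 1200 trials in 6 blocks of 200
#' (digit 250 ms, mask 900 ms, so 1.15 s onset asynchrony) and `"exp4"` with
#' 1080 trials in 4 blocks of 270.
#'
#' @param preset `"exp1"` or `"exp4"`.
#' @return list with `n_trials`, `n_blocks`, `digit_dur`, `mask_dur`,
#'   `target_prop`.
#' @export
sart_preset <- function(preset = c("exp1", "exp4")) {
  preset <- match.arg(preset)
  base <- list(digit_dur = 0.250, mask_dur = 0.900, target_prop = 0.10)
  if (preset == "exp1") c(list(n_trials = 1200L, n_blocks = 6L), base)
  else c(list(n_trials = 1080L, n_blocks = 4L), base)
}

#' Generate a SART trial schedule
#'
#' Go/no-go digit schedule: exactly `round(n_trials * target_prop)` no-go
#' targets (digit 0), positions randomized under an optional
#' no-consecutive-targets constraint, non-target digits uniform over 1-9.
#' Onset-to-onset interval is `digit_dur + mask_dur` throughout.
#'
#' @param n_trials total trials (divisible by `n_blocks`).
#' @param target_prop proportion of no-go targets in (0, 0.5); may be 0 for
#'   an all-go schedule (flagged: no d' computable).
#' @param digit_dur,mask_dur durations in seconds (defaults 0.250 / 0.900).
#' @param n_blocks number of equal blocks.
#' @param conditions optional character vector, one condition label per
#'   block (recycled if length 1).
#' @param no_consecutive_targets forbid adjacent targets (default TRUE).
#' @param seed RNG seed for reproducible schedules.
#' @return tibble of class `trial_schedule`: `trial`, `block`, `condition`,
#'   `digit`, `is_target`, `onset_s`, `digit_dur_s`, `mask_dur_s`.
#' @export
generate_schedule <- function(n_trials, target_prop = 0.10, digit_dur = 0.250,
                              mask_dur = 0.900, n_blocks = 1,
                              conditions = NULL, no_consecutive_targets = TRUE,
                              seed = NULL) {
  if (n_trials %% n_blocks != 0) {
    abort("`n_trials` must be divisible by `n_blocks`", class = "ammod_invalid_parameter")
  }
  if (target_prop < 0 || target_prop >= 0.5) {
    abort("`target_prop` must be in [0, 0.5)", class = "ammod_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- round(n_trials * target_prop)
  if (no_consecutive_targets && k > 0) {
    if (k > (n_trials + 1) %/% 2) {
      abort("no-consecutive-targets constraint infeasible", class = "ammod_schedule_infeasible")
    }
    # choose k non-adjacent positions uniformly: pick k of n-k+1 slots,
    # then shift by 0..k-1 to re-insert the mandatory gaps
    pos <- sort(sample.int(n_trials - k + 1, k)) + seq_len(k) - 1L
  } else {
    pos <- sort(sample.int(n_trials, k))
  }
  is_target <- rep(FALSE, n_trials)
  is_target[pos] <- TRUE
  digit <- sample(1:9, n_trials, replace = TRUE)
  digit[is_target] <- 0L
  if (k == 0) warn("all-go schedule: no d' computable")
  block <- rep(seq_len(n_blocks), each = n_trials / n_blocks)
  cond <- if (is.null(conditions)) rep("none", n_trials)
          else rep(rep(conditions, length.out = n_blocks), each = n_trials / n_blocks)
  out <- tibble(
    trial = seq_len(n_trials), block = block, condition = cond,
    digit = digit, is_target = is_target,
    onset_s = (seq_len(n_trials) - 1) * (digit_dur + mask_dur),
    digit_dur_s = digit_dur, mask_dur_s = mask_dur
  )
  class(out) <- c("trial_schedule", class(out))
  out
}

# z(hit) - z(fa) with the log-linear correction: 0.5 added to each count,
# 1 to each trial total, so perfect rates stay finite
dprime_loglinear <- function(hits, misses, fas, crs) {
  hr <- (hits + 0.5) / (hits + misses + 1)
  far <- (fas + 0.5) / (fas + crs + 1)
  qnorm(hr) - qnorm(far)
}

#' Score SART responses with signal-detection theory
#'
#' Trials are classified as hit (go, pressed), miss (go, not pressed),
#' false alarm (no-go, pressed) or correct rejection (no-go, not pressed),
#' and d' = z(hit rate) - z(false-alarm rate) is computed per block x
#' condition with the log-linear correction (0.5 added to each count, 1 to
#' each total), tagged in `correction_tag`.
#'
#' @param schedule a [generate_schedule()] tibble.
#' @param log a response log tibble with one row per trial: `pressed`
#'   (logical) and optionally `rt_s`, `subject`.
#' @return tibble of class `sdt_summary`: `subject`, `condition`, `block`,
#'   `hits`, `misses`, `false_alarms`, `correct_rejections`, `n_go`,
#'   `n_nogo`, `hit_rate`, `fa_rate`, `dprime`, `correction_tag`.
#' @export
score_responses <- function(schedule, log) {
  if (nrow(log) %% nrow(schedule) != 0) {
    abort("log length is not a multiple of schedule length", class = "ammod_invalid_input")
  }
  if (!"subject" %in% names(log)) log$subject <- "s1"
  n_sched <- nrow(schedule)
  df <- dplyr::bind_cols(
    schedule[rep(seq_len(n_sched), times = nrow(log) / n_sched),
             c("block", "condition", "is_target")],
    log[, intersect(c("subject", "pressed", "rt_s"), names(log))]
  )
  out <- df |>
    dplyr::group_by(.data$subject, .data$condition, .data$block) |>
    dplyr::summarise(
      hits = sum(!.data$is_target & .data$pressed),
      misses = sum(!.data$is_target & !.data$pressed),
      false_alarms = sum(.data$is_target & .data$pressed),
      correct_rejections = sum(.data$is_target & !.data$pressed),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_go = .data$hits + .data$misses,
      n_nogo = .data$false_alarms + .data$correct_rejections,
      hit_rate = (.data$hits + 0.5) / (.data$n_go + 1),
      fa_rate = (.data$false_alarms + 0.5) / (.data$n_nogo + 1),
      dprime = dprime_loglinear(.data$hits, .data$misses,
                                .data$false_alarms, .data$correct_rejections),
      correction_tag = "loglinear"
    )
  class(out) <- c("sdt_summary", class(out))
  out
}

#' Reaction-time coefficient of variation per trial window
#'
#' SD/mean of the reaction times within consecutive windows of `window`
#' trials (sample, n-1, standard deviation). Windows containing fewer than
#' two RTs yield `NA`.
#'
#' @param log response log tibble with `pressed` and `rt_s`.
#' @param window trials per window (default 10).
#' @return tibble: `window`, `n_rt`, `cv`.
#' @export
rt_variability <- function(log, window = 10) {
  rts <- ifelse(log$pressed, log$rt_s, NA_real_)
  if (all(is.na(rts))) abort("no reaction times in log", class = "ammod_insufficient_data")
  nw <- length(rts) %/% window
  if (nw < 1) abort("fewer trials than one window", class = "ammod_insufficient_data")
  purrr::map_dfr(seq_len(nw), function(w) {
    r <- rts[((w - 1) * window + 1):(w * window)]
    r <- r[!is.na(r)]
    tibble(window = w, n_rt = length(r),
           cv = if (length(r) >= 2) sd(r) / mean(r) else NA_real_)
  })
}

#' Per-subject d-prime differences relative to a baseline condition
#'
#' For every subject x condition x block cell, the d' difference relative to
#' the baseline (no-modulation) condition in the matching block. Because
#' each block carries one condition, "matching" means the same presentation
#' position within the condition: each condition's blocks are ordered and
#' indexed 1, 2, ... (early, late, ...), and the k-th block of a condition
#' is compared with the k-th block of the baseline.
#'
#' @param summaries an [score_responses()] tibble covering >= 2 conditions
#'   per subject, baseline included.
#' @param baseline baseline condition label (default `"none"`).
#' @return tibble of class `ddprime_table`: `subject`, `condition`, `block`
#'   (the within-condition position, 1 = earliest) and `ddprime`.
#' @export
condition_block_summary <- function(summaries, baseline = "none") {
  if (!baseline %in% summaries$condition) {
    abort("baseline condition missing", class = "ammod_invalid_input")
  }
  indexed <- summaries |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::arrange(.data$block, .by_group = TRUE) |>
    dplyr::mutate(.rep = dplyr::row_number()) |>
    dplyr::ungroup()
  base <- indexed |>
    dplyr::filter(.data$condition == baseline) |>
    dplyr::select("subject", ".rep", base_dprime = "dprime")
  miss <- setdiff(unique(summaries$subject), unique(base$subject))
  if (length(miss)) {
    abort(paste("subjects lack the baseline condition:", paste(miss, collapse = ", ")),
          class = "ammod_invalid_input")
  }
  out <- indexed |>
    dplyr::filter(.data$condition != baseline) |>
    dplyr::inner_join(base, by = c("subject", ".rep")) |>
    dplyr::transmute(.data$subject, .data$condition, block = .data$.rep,
                     ddprime = .data$dprime - .data$base_dprime)
  class(out) <- c("ddprime_table", class(out))
  out
}

#' Group means with within-subject (Cousineau-Morey) SEM
#'
#' Each subject's cell values are centered on the subject mean (plus the
#' grand mean) before the SEM is computed, and the result is inflated by the
#' Morey factor `sqrt(m / (m - 1))` for `m` cells, giving error bars that
#' reflect within-subject variability only.
#'
#' @param ddprime a [condition_block_summary()] tibble (or any tibble with
#'   `subject`, `condition`, `block` and a value column).
#' @param value name of the value column (default `"ddprime"`).
#' @return tibble: `condition`, `block`, `mean`, `sem_ws`, `n`.
#' @export
condition_means <- function(ddprime, value = "ddprime") {
  v <- ddprime[[value]]
  grand <- mean(v)
  d <- ddprime |>
    dplyr::mutate(.value = v) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(.centered = .data$.value - mean(.data$.value) + grand) |>
    dplyr::ungroup()
  m <- nrow(dplyr::distinct(ddprime, .data$condition, .data$block))
  morey <- sqrt(m / (m - 1))
  d |>
    dplyr::group_by(.data$condition, .data$block) |>
    dplyr::summarise(
      mean = mean(.data$.value),
      sem_ws = sd(.data$.centered) / sqrt(dplyr::n()) * morey,
      n = dplyr::n(), .groups = "drop"
    )
}

#' Rate x block x attentional-difficulty interaction contrast
#'
#' Per subject, the scalar contrast
#' `c = sum_rate q(rate) * sum_block l(block) * ddprime(rate, block)` with
#' quadratic rate weights `q = (-1, +2, -1)` over (8, 16, 32) Hz — peaking
#' at the medium 16 Hz rate — and linear block weights `l = (-1, +1)` over
#' (early, late). The statistic is the regression slope of `c` on centered
#' ASRS score; significance is assessed by permuting ASRS labels across
#' subjects. This is a deliberate re-operationalization of a repeated-
#' measures mixed-effects ANOVA interaction as a per-subject contrast plus
#' permutation test; it is tagged in the output.
#'
#' @param ddprime a [condition_block_summary()] tibble whose `condition`
#'   encodes the modulation rate.
#' @param profiles tibble with `subject` and `asrs_score`.
#' @param rate_levels rate conditions in order (default `c("8","16","32")`).
#' @param q_weights quadratic contrast weights (default `c(-1, 2, -1)`).
#' @param block_weights linear block weights over early/late halves.
#' @param n_perm number of label permutations (default 1999).
#' @param seed RNG seed for the permutation draw.
#' @return object of class `am_contrast`: list with `estimate` (slope per
#'   unit ASRS), `p_value` (two-sided permutation p), `n_subjects`,
#'   `n_perm`, `method` tag and `subject_contrasts` tibble.
#' @export
interaction_contrast <- function(ddprime, profiles, rate_levels = c("8", "16", "32"),
                                 q_weights = c(-1, 2, -1), block_weights = c(-1, 1),
                                 n_perm = 1999, seed = NULL) {
  blocks <- sort(unique(ddprime$block))
  if (length(blocks) < 2) abort("need >= 2 blocks", class = "ammod_insufficient_data")
  # collapse blocks into early/late halves by index
  half <- stats::setNames(ifelse(seq_along(blocks) <= length(blocks) / 2, "early", "late"), blocks)
  d <- ddprime |>
    dplyr::mutate(condition = as.character(.data$condition),
                  phase = half[as.character(.data$block)]) |>
    dplyr::filter(.data$condition %in% rate_levels) |>
    dplyr::group_by(.data$subject, .data$condition, .data$phase) |>
    dplyr::summarise(ddprime = mean(.data$ddprime), .groups = "drop")

  qw <- stats::setNames(q_weights, rate_levels)
  lw <- stats::setNames(block_weights, c("early", "late"))
  cells_needed <- length(rate_levels) * 2
  cs <- d |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      complete = dplyr::n() == cells_needed,
      contrast = sum(qw[.data$condition] * lw[.data$phase] * .data$ddprime),
      .groups = "drop"
    )
  if (any(!cs$complete)) {
    warn(sprintf("%d subject(s) with missing cells excluded", sum(!cs$complete)))
    cs <- cs[cs$complete, ]
  }
  cs <- dplyr::inner_join(cs, profiles, by = "subject")
  if (nrow(cs) < 3) abort("too few complete subjects", class = "ammod_insufficient_data")

  x <- cs$asrs_score - mean(cs$asrs_score)
  y <- cs$contrast
  sxx <- sum(x^2)
  if (sxx == 0) abort("no ASRS variance", class = "ammod_insufficient_data")
  slope <- sum(x * y) / sxx
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, {
    xp <- sample(x)
    sum(xp * y) / sxx
  })
  p <- (1 + sum(abs(perm) >= abs(slope))) / (n_perm + 1)
  structure(
    list(estimate = slope, p_value = p, n_subjects = nrow(cs), n_perm = n_perm,
         method = "per-subject quadratic(rate) x linear(block) contrast, ASRS slope, permutation test",
         subject_contrasts = cs),
    class = "am_contrast"
  )
}

#' @export
print.am_contrast <- function(x, ...) {
  cat(sprintf(
    "<am_contrast> slope = %.4f per ASRS unit, permutation p = %.4f (n = %d, %d perms)\n  %s\n",
    x$estimate, x$p_value, x$n_subjects, x$n_perm, x$method
  ))
  invisible(x)
}

#' Write / read trial tables
#'
#' Schedules, logs and summaries are plain TSV with one row per trial or
#' cell.
#'
#' @param x a tibble; `path` the TSV path.
#' @return `path` invisibly / a tibble.
#' @export
write_trials <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}
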