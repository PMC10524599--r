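#' Design a synthetic dequenching plate
#'
#' Describes a family of fluorescence-dequenching disassembly reactions
#' for [sim_plate()]. The default condition table emulates the
#' qualitative outcome of the NSF I209N disassembly experiments: for the
#' ternary (syntaxin-1A + SNAP-25 + synaptobrevin-2) SNARE substrate the
#' mutant is far slower than WT at both NSF concentrations and
#' essentially inactive at 8.3 nM; for the binary substrate the mutant
#' is only slightly slower at 42.2 nM but strongly impaired at 8.3 nM.
#' A no-NSF control per substrate stays flat. Reaction metadata (NSF :
#' SNARE : alpha-SNAP combined at 1:5:25 molar ratio, 1720 nM labelled
#' SNARE, 1.96 uM alpha-SNAP, 60 uL) is carried as annotation only —
#' the generator is phenomenological, not mechanistic.
#'
#' @param conditions Tibble with columns `variant` (`"WT"`, `"I209N"`,
#'   `"none"`), `nsf_nM` (8.3, 42.2, or 0 for `"none"`),
#'   `complex_kind` (`"ternary"`, `"binary"`), `k_obs` (per s),
#'   `f0_au`, `fmax_au`, `drift_au_per_s`. Default described above.
#' @param replicates Replicate traces per condition (>= 1; default 3).
#' @param duration_s Trace length, seconds.
#' @param sample_interval_s Plate-reader read interval, seconds
#'   (default 2.5, so the 112.5 s / 222.5 s rate windows hold 45 / 89
#'   points).
#' @param noise_sd_au Gaussian read-noise SD, arbitrary units.
#' @return A `plate_design` object.
#' @export
plate_design <- function(conditions = NULL, replicates = 3,
                         duration_s = 600, sample_interval_s = 2.5,
                         noise_sd_au = 1) {
  if (is.null(conditions)) {
    conditions <- tibble(
      variant = rep(c("WT", "I209N", "WT", "I209N", "none"), 2),
      nsf_nM = rep(c(42.2, 42.2, 8.3, 8.3, 0), 2),
      complex_kind = rep(c("ternary", "binary"), each = 5),
      k_obs = c(0.020, 0.002, 0.008, 0.0002, 0,
                0.004, 0.003, 0.0015, 0.0002, 0),
      f0_au = 100, fmax_au = 200, drift_au_per_s = 0.002)
    conditions$drift_au_per_s[conditions$variant == "none"] <- 0
  }
  req <- c("variant", "nsf_nM", "complex_kind", "k_obs", "f0_au",
           "fmax_au", "drift_au_per_s")
  if (!all(req %in% names(conditions))) {
    abort(paste("`conditions` must have columns:", paste(req, collapse = ", ")),
          class = "afferent_bad_argument")
  }
  if (replicates < 1) abort("Need replicates >= 1.",
                            class = "afferent_bad_argument")
  if (any(conditions$k_obs < 0) ||
      any(conditions$fmax_au < conditions$f0_au)) {
    abort("Invalid conditions: need k_obs >= 0 and fmax_au >= f0_au.",
          class = "afferent_bad_argument")
  }
  if (!all((conditions$nsf_nM == 0) == (conditions$variant == "none"))) {
    abort("nsf_nM must be 0 exactly for the no-NSF (`variant = \"none\"`) control.",
          class = "afferent_bad_argument")
  }
  structure(
    list(conditions = as_tibble(conditions), replicates = as.integer(replicates),
         duration_s = duration_s, sample_interval_s = sample_interval_s,
         noise_sd_au = noise_sd_au,
         metadata = list(molar_ratio = "NSF:SNARE:alphaSNAP = 1:5:25",
                         snare_nM = 1720, alpha_snap_uM = 1.96,
                         volume_uL = 60)),
    class = "plate_design")
}

#' Simulate plate-reader dequenching traces
#'
#' Each (condition, replicate) cell yields a saturating fluorescence
#' trace `F(t) = f0 + (fmax - f0) * (1 - exp(-k_obs * t)) + drift * t`
#' plus Gaussian read noise; replicate traces share the noiseless
#' backbone and differ only in their noise stream. The rising
#' fluorescence reports SNARE-complex disassembly: the dye self-quenches
#' on the assembled complex and dequenches as NSF/alpha-SNAP pull it
#' apart.
#'
#' @param design A [plate_design()].
#' @param seed Integer seed.
#' @return A `plate` tibble in long format: `time_s`,
#'   `fluorescence_au`, `variant`, `nsf_nM`, `complex_kind`,
#'   `replicate`.
#' @export
sim_plate <- function(design, seed = 0) {
  stopifnot(inherits(design, "plate_design"))
  tt <- seq(0, design$duration_s, by = design$sample_interval_s)
  cells <- tidyr::expand_grid(cond = seq_len(nrow(design$conditions)),
                              replicate = seq_len(design$replicates))
  out <- with_seed(seed, {
    pmap(cells, function(cond, replicate) {
      cd <- design$conditions[cond, ]
      backbone <- cd$f0_au +
        (cd$fmax_au - cd$f0_au) * (1 - exp(-cd$k_obs * tt)) +
        cd$drift_au_per_s * tt
      noise <- if (design$noise_sd_au > 0) {
        rnorm(length(tt), sd = design$noise_sd_au)
      } else 0
      tibble(time_s = tt, fluorescence_au = backbone + noise,
             variant = cd$variant, nsf_nM = cd$nsf_nM,
             complex_kind = cd$complex_kind, replicate = replicate)
    }) |> list_rbind()
  })
  structure(out, class = c("plate", class(tibble())),
            design = design, seed = seed)
}

#' Read plate-reader kinetics from long-format CSV
#'
#' Expects columns `time_s, fluorescence_au, variant, nsf_nM,
#' complex_kind, replicate`. Rows are sorted into traces by condition
#' and replicate, time is re-zeroed to each trace's first sample, and
#' the condition vocabulary is validated: `complex_kind` must be
#' `"ternary"` or `"binary"`, and `nsf_nM` must be one of 0, 8.3 or
#' 42.2 unless `allow_any_concentration` is set. Errors cite the
#' offending row numbers.
#'
#' @param path CSV path.
#' @param allow_any_concentration Accept NSF concentrations outside the
#'   assay's {0, 8.3, 42.2} nM vocabulary.
#' @return A `plate` tibble.
#' @export
read_plate <- function(path, allow_any_concentration = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("time_s", "fluorescence_au", "variant", "nsf_nM",
           "complex_kind", "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste("Plate CSV is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "afferent_bad_plate")
  }
  bad_kind <- which(!df$complex_kind %in% c("ternary", "binary"))
  if (length(bad_kind)) {
    abort(sprintf("Unknown complex_kind at data row(s) %s (allowed: ternary, binary).",
                  paste(utils::head(bad_kind, 5), collapse = ", ")),
          class = "afferent_bad_plate")
  }
  if (!allow_any_concentration) {
    bad_conc <- which(!df$nsf_nM %in% c(0, 8.3, 42.2))
    if (length(bad_conc)) {
      abort(sprintf(
        "nsf_nM outside {0, 8.3, 42.2} at data row(s) %s; set allow_any_concentration = TRUE to accept.",
        paste(utils::head(bad_conc, 5), collapse = ", ")),
        class = "afferent_bad_plate")
    }
  }
  if (!all((df$nsf_nM == 0) == (df$variant == "none"))) {
    abort("nsf_nM must be 0 exactly for variant \"none\" rows.",
          class = "afferent_bad_plate")
  }
  out <- df |>
    arrange(.data$complex_kind, .data$variant, .data$nsf_nM,
            .data$replicate, .data$time_s) |>
    group_by(.data$variant, .data$nsf_nM, .data$complex_kind,
             .data$replicate) |>
    mutate(time_s = .data$time_s - min(.data$time_s)) |>
    ungroup()
  nonmono <- out |>
    group_by(.data$variant, .data$nsf_nM, .data$complex_kind,
             .data$replicate) |>
    summarise(mono = all(diff(.data$time_s) > 0), .groups = "drop")
  if (!all(nonmono$mono)) {
    abort("Non-monotone (duplicated) time points within a trace.",
          class = "afferent_bad_plate")
  }
  structure(out[req], class = c("plate", class(tibble())))
}

#' Initial disassembly rate of one dequenching trace
#'
#' Ordinary least-squares slope of fluorescence versus time over the
#' initial window `[0, window_s]`, with the slope's standard error from
#' the regression. Time zero is trituration with the initiation
#' solution (the first sample). The default window follows the
#' substrate: 112.5 s for ternary complexes, 222.5 s for the slower
#' binary complexes. No baseline normalization is applied: rates are in
#' raw fluorescence units per second.
#'
#' @param trace Tibble with `time_s`, `fluorescence_au` for one trace;
#'   at least 3 samples must fall inside the window.
#' @param window_s Window length, seconds; default by `complex_kind`
#'   when the trace carries one, else required.
#' @return One-row tibble `slope_au_per_s`, `slope_se`, `window_s`,
#'   `n_points`.
#' @export
initial_rate <- function(trace, window_s = NULL) {
  if (is.null(window_s)) {
    kind <- unique(trace$complex_kind)
    if (length(kind) == 1 && kind %in% names(rate_windows())) {
      window_s <- rate_windows()[[kind]]
    } else {
      abort("Supply `window_s` (no complex_kind on the trace).",
            class = "afferent_bad_argument")
    }
  }
  check_number(window_s, "window_s", lower = 0)
  t0 <- min(trace$time_s)
  sub <- trace[trace$time_s - t0 <= window_s, ]
  if (nrow(sub) < 3) {
    abort("Need at least 3 samples inside the initial-rate window.",
          class = "afferent_bad_argument")
  }
  fit <- lm(fluorescence_au ~ time_s, data = sub)
  sm <- summary(fit)$coefficients
  tibble(slope_au_per_s = sm["time_s", "Estimate"],
         slope_se = sm["time_s", "Std. Error"],
         window_s = window_s, n_points = nrow(sub))
}

rate_windows <- function() c(ternary = 112.5, binary = 222.5)

#' Initial rates for every trace on a plate
#'
#' Applies [initial_rate()] per (condition, replicate) trace with the
#' substrate-specific default windows.
#'
#' @param plate A `plate` tibble.
#' @param window_ternary_s,window_binary_s Window overrides, seconds.
#' @return A `rate_table` tibble: one row per trace with the condition
#'   columns plus `slope_au_per_s`, `slope_se`, `window_s`, `n_points`.
#' @export
initial_rates <- function(plate, window_ternary_s = 112.5,
                          window_binary_s = 222.5) {
  wins <- c(ternary = window_ternary_s, binary = window_binary_s)
  out <- plate |>
    group_by(.data$variant, .data$nsf_nM, .data$complex_kind,
             .data$replicate) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(rate = map2(.data$data, .data$complex_kind,
                       function(d, k) initial_rate(d, wins[[k]]))) |>
    dplyr::select(-"data") |>
    tidyr::unnest("rate")
  structure(out, class = c("rate_table", class(tibble())))
}

#' Compare initial rates across conditions
#'
#' One-way ANOVA (or a two-tailed t test for exactly two groups) of
#' replicate initial rates across the levels of a grouping column,
#' typically `variant` within one (substrate, concentration) panel.
#' Every group needs at least 2 replicates.
#'
#' @param rates A `rate_table` (or tibble with `slope_au_per_s`).
#' @param group Name of the grouping column (default `"variant"`).
#' @param test `"one_way_anova"` (default) or `"t_test_two_tailed"`
#'   (two groups only).
#' @return One-row tibble `test`, `statistic`, `df_num`, `df_den`, `p`,
#'   `groups`.
#' @export
compare_rates <- function(rates, group = "variant",
                          test = c("one_way_anova", "t_test_two_tailed")) {
  test <- match.arg(test)
  g <- factor(rates[[group]])
  sizes <- table(g)
  if (length(sizes) < 2) abort("Need at least 2 groups.",
                               class = "afferent_bad_argument")
  if (any(sizes < 2)) {
    abort(sprintf("Group(s) with a single replicate: %s.",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "afferent_bad_argument")
  }
  y <- rates$slope_au_per_s
  if (test == "t_test_two_tailed") {
    if (length(sizes) != 2) {
      abort("t test needs exactly 2 groups.", class = "afferent_bad_argument")
    }
    tt <- t.test(y ~ g)
    tibble(test = test, statistic = unname(tt$statistic),
           df_num = NA_real_, df_den = unname(tt$parameter),
           p = tt$p.value,
           groups = paste(levels(g), collapse = " vs "))
  } else {
    sm <- summary(aov(y ~ g))[[1]]
    tibble(test = test, statistic = sm["g", "F value"],
           df_num = sm["g", "Df"], df_den = sm["Residuals", "Df"],
           p = sm["g", "Pr(>F)"],
           groups = paste(levels(g), collapse = " vs "))
  }
}

#' @export
autoplot.plate <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_s, y = .data$fluorescence_au,
                               colour = .data$variant,
                               group = interaction(.data$variant,
                                                   .data$nsf_nM,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_grid(.data$complex_kind ~ .data$nsf_nM,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time after trituration (s)",
                  y = "fluorescence (AU)") +
    ggplot2::theme_minimal()
}
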