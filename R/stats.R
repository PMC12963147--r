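#' Bland-Altman agreement between two end-tidal measurement methods
#'
#' Classical Bland-Altman analysis of paired per-breath end-tidal
#' concentrations: bias is the mean of the differences (device - monitor)
#' and the limits of agreement are bias +/- 1.96 times their sample
#' standard deviation. Pairs with a missing member are dropped.
#'
#' @param device_ec Per-breath end-tidal concentrations from the delivery
#'   device (vol%).
#' @param monitor_ec Paired values from the external gas monitor (vol%).
#' @return An object of class `bland_altman`: `bias`, `loa_low`, `loa_high`
#'   (vol%), `sd_diff`, `n`, and a data.frame `pairs` with columns `mean`
#'   and `difference` for plotting.
#' @examples
#' ba <- bland_altman(c(1.0, 1.2, 1.1), c(1.05, 1.15, 1.1))
#' ba$bias
#' @export
bland_altman <- function(device_ec, monitor_ec) {
  stopifnot(is.numeric(device_ec), is.numeric(monitor_ec))
  if (length(device_ec) != length(monitor_ec))
    stop("device_ec and monitor_ec must be paired (equal length)")
  ok <- !is.na(device_ec) & !is.na(monitor_ec)
  x <- device_ec[ok]; y <- monitor_ec[ok]
  if (length(x) < 2) stop("Bland-Altman analysis needs at least 2 complete pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 pairs = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f vol%%, limits of agreement [%.4f, %.4f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Polynomial regression of consumption on end-tidal concentration
#'
#' Fits, per experiment group, a least-squares polynomial (default degree
#' 2) of hourly liquid consumption on mean end-tidal concentration, and
#' tests pairwise group contrasts with a pooled linear model carrying the
#' polynomial terms plus a group indicator (the group main effect is
#' tested). Exclusions (e.g. the highest targets of the more potent agent,
#' to keep the compared concentration ranges comparable) are applied before
#' fitting and contrasts.
#'
#' @param records A data.frame with columns `group`, `mean_ec` (vol%) and
#'   `hourly_rate_ml_h`; typically [average_up_down()] outputs bound
#'   together with a `group` label per experiment.
#' @param degree Polynomial degree (default 2).
#' @param exclusions Optional data.frame with columns `group` and
#'   `target_volpct`: rows of `records` matching (group, target_volpct)
#'   are dropped before fitting (requires a `target_volpct` column).
#' @return An object of class `consumption_fit`: `coefficients` (named list
#'   of per-group coefficient vectors, intercept first), `fits` (the lm
#'   objects), `contrasts` (data.frame `group1`, `group2`, `p_value`),
#'   `degree`, `data` (rows used).
#' @export
fit_consumption <- function(records, degree = 2, exclusions = NULL) {
  stopifnot(is.data.frame(records),
            all(c("group", "mean_ec", "hourly_rate_ml_h") %in% names(records)))
  if (degree < 1) stop("degree must be at least 1")
  records <- records[!is.na(records$mean_ec) & !is.na(records$hourly_rate_ml_h), ,
                     drop = FALSE]
  if (!is.null(exclusions)) {
    stopifnot(all(c("group", "target_volpct") %in% names(exclusions)),
              "target_volpct" %in% names(records))
    drop <- interaction(records$group, round(records$target_volpct, 6)) %in%
      interaction(exclusions$group, round(exclusions$target_volpct, 6))
    records <- records[!drop, , drop = FALSE]
  }
  records$group <- factor(records$group)
  groups <- levels(records$group)

  fits <- list(); coefs <- list()
  for (g in groups) {
    r <- records[records$group == g, , drop = FALSE]
    if (nrow(r) < degree + 2)
      stop(sprintf("group '%s' has %d points; at least %d needed for degree %d",
                   g, nrow(r), degree + 2, degree))
    fit <- stats::lm(hourly_rate_ml_h ~ poly(mean_ec, degree, raw = TRUE), data = r)
    if (anyNA(stats::coef(fit)))
      stop(sprintf("rank-deficient polynomial design in group '%s'", g))
    fits[[g]] <- fit
    cf <- stats::coef(fit)
    names(cf) <- c("intercept", paste0("ec^", seq_len(degree)))
    coefs[[g]] <- cf
    # diagnostic: the fitted consumption curve should not go negative
    xs <- seq(min(r$mean_ec), max(r$mean_ec), length.out = 101)
    yhat <- drop(cbind(1, outer(xs, seq_len(degree), `^`)) %*% stats::coef(fit))
    if (any(yhat < 0))
      warning(sprintf(
        "group '%s': fitted consumption curve dips below zero within the observed EC range",
        g))
  }

  contrasts <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    contrasts <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                            p_value = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      r <- records[records$group %in% pairs[, i], , drop = FALSE]
      r$group <- droplevels(r$group)
      full <- stats::lm(hourly_rate_ml_h ~ poly(mean_ec, degree, raw = TRUE) + group,
                        data = r)
      base <- stats::lm(hourly_rate_ml_h ~ poly(mean_ec, degree, raw = TRUE),
                        data = r)
      contrasts$p_value[i] <- stats::anova(base, full)[2, "Pr(>F)"]
    }
  }
  structure(list(coefficients = coefs, fits = fits, contrasts = contrasts,
                 degree = degree, data = records),
            class = "consumption_fit")
}

#' @export
print.consumption_fit <- function(x, ...) {
  cat(sprintf("Consumption regression (degree %d), %d group(s)\n",
              x$degree, length(x$coefficients)))
  for (g in names(x$coefficients)) {
    cat(sprintf("  %s: %s\n", g,
                paste(sprintf("%s = %.4g", names(x$coefficients[[g]]),
                              x$coefficients[[g]]), collapse = ", ")))
  }
  if (!is.null(x$contrasts)) {
    for (i in seq_len(nrow(x$contrasts)))
      cat(sprintf("  contrast %s vs %s: p = %.4g\n", x$contrasts$group1[i],
                  x$contrasts$group2[i], x$contrasts$p_value[i]))
  }
  invisible(x)
}

#' Predict hourly consumption from a fitted group polynomial
#'
#' @param object A `consumption_fit`.
#' @param group Group label.
#' @param ec End-tidal concentrations (vol%) at which to evaluate.
#' @param ... Unused.
#' @return Predicted hourly consumption (mL/h).
#' @export
predict_consumption <- function(object, group, ec, ...) {
  stopifnot(inherits(object, "consumption_fit"))
  cf <- object$coefficients[[group]]
  if (is.null(cf)) stop(sprintf("no fit for group '%s'", group))
  drop(cbind(1, outer(ec, seq_len(object$degree), `^`)) %*% cf)
}

#' Render the analysis report bundle
#'
#' Writes, for whichever inputs are supplied, CSV/plot pairs mirroring the
#' standard bench readouts: the end-tidal concentration time course with
#' the target staircase and per-target means; Bland-Altman agreement
#' panels; the consumption-vs-concentration table with fitted curves; and
#' reflection efficiency over vapour volume per exhaled breath. Sections
#' whose inputs are missing are skipped with a notice. CSVs are the data of
#' record; plots are conveniences.
#'
#' @param outdir Output directory (created if missing).
#' @param breaths Optional `breath_records` (with `device_log` + `schedule`
#'   + `agent` enables the time-course section).
#' @param device_log Optional device log data.frame.
#' @param schedule Optional [target_schedule()].
#' @param vent Optional [vent_settings()] (for breath timing).
#' @param agent Optional [agent_spec()].
#' @param agreement Optional [bland_altman()] result.
#' @param efficiency Optional `efficiency_records` per-period table.
#' @param averaged Optional [average_up_down()] per-target table.
#' @param fit Optional [fit_consumption()] result.
#' @param formats Character vector, subset of `c("csv", "png")`.
#' @return Invisibly, a character vector of the files written.
#' @export
render_report <- function(outdir, breaths = NULL, device_log = NULL,
                          schedule = NULL, vent = NULL, agent = NULL,
                          agreement = NULL, efficiency = NULL,
                          averaged = NULL, fit = NULL,
                          formats = c("csv", "png")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit_csv <- function(df, name) {
    if (!"csv" %in% formats) return()
    path <- file.path(outdir, paste0(name, ".csv"))
    write_csv_atomic(round_numeric(df, 4), path)
    written <<- c(written, path)
  }
  emit_plot <- function(p, name, width = 7, height = 4.5) {
    if (!"png" %in% formats) return()
    path <- file.path(outdir, paste0(name, ".png"))
    ok <- tryCatch({
      grDevices::png(path, width = width * 100, height = height * 100, res = 100)
      print(p); grDevices::dev.off(); TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      message("plot '", name, "' skipped: ", conditionMessage(e)); FALSE
    })
    if (ok) written <<- c(written, path)
  }

  if (!is.null(breaths) && !is.null(schedule) && !is.null(vent)) {
    t_s <- breaths$expiration_onset_ms / 1000
    tc <- data.frame(t_min = t_s / 60,
                     monitor_ec_volpct = breaths$ec_volpct,
                     target_volpct = schedule_target_at(schedule, t_s, agent))
    if (!is.null(device_log) && nrow(device_log) >= nrow(tc))
      tc$device_ec_volpct <- device_log$device_ec_volpct[seq_len(nrow(tc))]
    emit_csv(tc, "ec_timecourse")
    idx <- findInterval(t_s, schedule$t_start)
    idx[t_s >= schedule$t_end[nrow(schedule)]] <- nrow(schedule)
    means <- data.frame(
      period = seq_len(nrow(schedule)),
      target_volpct = if (!is.null(agent)) mac_to_volpct(schedule$fraction, agent)
                      else schedule$fraction,
      mean_ec_volpct = vapply(seq_len(nrow(schedule)), function(p)
        mean(breaths$ec_volpct[idx == p], na.rm = TRUE), numeric(1)))
    emit_csv(means, "ec_target_means")
    p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$t_min)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$monitor_ec_volpct), colour = "grey40") +
      ggplot2::geom_step(ggplot2::aes(y = .data$target_volpct), colour = "black") +
      ggplot2::labs(x = "time [min]", y = "end-tidal concentration [vol%]",
                    title = "End-tidal concentration vs target staircase")
    emit_plot(p, "ec_timecourse")
  } else message("report: time-course section skipped (breaths/schedule missing)")

  if (!is.null(agreement)) {
    emit_csv(data.frame(bias = agreement$bias, sd_diff = agreement$sd_diff,
                        loa_low = agreement$loa_low, loa_high = agreement$loa_high,
                        n = agreement$n), "bland_altman_summary")
    emit_csv(agreement$pairs, "bland_altman_pairs")
    p <- ggplot2::ggplot(agreement$pairs,
                         ggplot2::aes(x = .data$mean, y = .data$difference)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_hline(yintercept = c(agreement$bias, agreement$loa_low,
                                         agreement$loa_high),
                          linetype = c("solid", "dashed", "dashed")) +
      ggplot2::labs(x = "mean of methods [vol%]", y = "difference [vol%]",
                    title = "Agreement of device vs monitor end-tidal values")
    emit_plot(p, "bland_altman")
  } else message("report: agreement section skipped")

  if (!is.null(efficiency)) emit_csv(efficiency, "efficiency_periods")
  else message("report: efficiency section skipped")

  if (!is.null(averaged)) {
    emit_csv(averaged, "efficiency_targets")
    keep <- !averaged$low_target & !is.na(averaged$re_percent)
    if (any(keep)) {
      p <- ggplot2::ggplot(averaged[keep, ],
                           ggplot2::aes(x = .data$vapour_per_breath_ml,
                                        y = .data$re_percent)) +
        ggplot2::geom_point() + ggplot2::geom_line() +
        ggplot2::labs(x = "vapour volume per exhaled breath [mL]",
                      y = "reflection efficiency [%]",
                      title = "Reflection efficiency vs vapour per breath")
      emit_plot(p, "re_vs_vapour")
    }
  }

  if (!is.null(fit)) {
    dat <- fit$data
    emit_csv(dat[, c("group", "mean_ec", "hourly_rate_ml_h")], "consumption_points")
    cf <- do.call(rbind, lapply(names(fit$coefficients), function(g)
      data.frame(group = g, term = names(fit$coefficients[[g]]),
                 estimate = unname(fit$coefficients[[g]]))))
    emit_csv(cf, "consumption_fit_coefficients")
    if (!is.null(fit$contrasts)) emit_csv(fit$contrasts, "consumption_contrasts")
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_ec,
                                           y = .data$hourly_rate_ml_h,
                                           colour = .data$group)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm",
                           formula = y ~ poly(x, fit$degree, raw = TRUE),
                           se = FALSE, linewidth = 0.6) +
      ggplot2::labs(x = "mean end-tidal concentration [vol%]",
                    y = "hourly consumption [mL liquid/h]",
                    title = "Consumption vs end-tidal concentration")
    emit_plot(p, "consumption_fit")
  }

  invisible(written)
}
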