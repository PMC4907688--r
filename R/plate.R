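## 384-well plate layout, drug library, end-to-end plate simulation and
## screen analysis.

.well_ids <- function() {
  rows <- LETTERS[1:16]
  as.vector(outer(rows, 1:24, function(r, c) paste0(r, c)))
}

#' Build the standard 384-well screening plate map
#'
#' Layout of the optical sodium-channel screen: columns 1 and 24 are left
#' empty (the scan runs from well A2 to P23, column-wise); columns 2 and 23
#' carry the controls, rows A-H with DMSO vehicle (negative) and rows I-P
#' with 10 uM amitriptyline (positive) at both ends of the plate; the 320
#' test wells A3-P22 are filled column-wise from the compound library.  If
#' the library is smaller than the test-well count the remaining wells are
#' marked empty.
#'
#' @param library A [drug_library()] (or `NULL` for an all-empty test area).
#' @param control_concentration Positive-control concentration (uM).
#' @return A data.frame of class `plate_map` with columns `well`, `row`,
#'   `column`, `compound`, `concentration_uM`, `role`, `scan_order`.
#' @export
build_plate_map <- function(library = drug_library(),
                            control_concentration = 10) {
  rows <- LETTERS[1:16]
  df <- data.frame(well = .well_ids(),
                   row = rep(rows, 24),
                   column = rep(1:24, each = 16),
                   compound = NA_character_,
                   concentration_uM = 0,
                   role = "empty",
                   stringsAsFactors = FALSE)
  ctrl <- df$column %in% c(2, 23)
  neg <- ctrl & df$row %in% rows[1:8]
  pos <- ctrl & df$row %in% rows[9:16]
  df$role[neg] <- "negative_control"
  df$compound[neg] <- "DMSO"
  df$role[pos] <- "positive_control"
  df$compound[pos] <- "amitriptyline"
  df$concentration_uM[pos] <- control_concentration

  test <- df$column >= 3 & df$column <= 22
  test_wells <- which(test)[order(df$column[test], match(df$row[test], rows))]
  n_lib <- if (is.null(library)) 0 else nrow(library$table)
  n_fill <- min(length(test_wells), n_lib)
  if (n_fill > 0) {
    idx <- test_wells[seq_len(n_fill)]
    df$role[idx] <- "test"
    df$compound[idx] <- library$table$label[seq_len(n_fill)]
    df$concentration_uM[idx] <- library$table$concentration[seq_len(n_fill)]
  }
  # column-wise scan order from A2 to P23
  scanned <- df$column >= 2 & df$column <= 23
  df$scan_order <- NA_integer_
  df$scan_order[scanned] <- order(order(df$column[scanned],
                                        match(df$row[scanned], rows)))
  class(df) <- c("plate_map", "data.frame")
  attr(df, "library") <- library
  df
}

#' @export
print.plate_map <- function(x, ...) {
  cat(sprintf(
    "384-well plate map: %d negative / %d positive controls, %d test, %d empty\n",
    sum(x$role == "negative_control"), sum(x$role == "positive_control"),
    sum(x$role == "test"), sum(x$role == "empty")))
  invisible(x)
}

#' Synthetic compound library
#'
#' Generates a screening library emulating a plate of approved drugs at a
#' single concentration, with compounds drawn from the five mechanistic
#' classes the simulator supports.  Default class mix: 12% of compounds are
#' "active" use-dependent sodium-channel blockers (60% slow-unbinding,
#' 40% fast-unbinding), plus small fractions of tonic blockers and
#' inactivation-curve shifters among the inert majority.  Per-compound
#' kinetic constants are jittered log-normally (20% CV) around the class
#' presets so the library is not five identical drugs.
#'
#' @param n Number of compounds.
#' @param concentration Screening concentration (uM).
#' @param fractions Named class fractions (`inert`, `tonic`, `slow_unbind`,
#'   `fast_unbind`, `gating_shift`); must sum to 1.
#' @param seed Integer seed for composition and jitter.
#' @return An object of class `drug_library`: a list with `table`
#'   (label, class, concentration, active flag) and `models` (named list of
#'   [drug_model()] objects).
#' @export
drug_library <- function(n = 320, concentration = 10,
                         fractions = c(inert = 0.78, tonic = 0.05,
                                       slow_unbind = 0.072,
                                       fast_unbind = 0.048,
                                       gating_shift = 0.05),
                         seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("class fractions must sum to 1")
  set.seed(as.integer(seed))
  counts <- round(fractions * n)
  counts["inert"] <- counts["inert"] + (n - sum(counts))  # absorb rounding
  classes <- sample(rep(names(counts), counts))
  labels <- sprintf("cmpd-%03d", seq_len(n))
  jit <- function(x, cv = 0.2) x * exp(rnorm(1, 0, cv))
  models <- lapply(seq_len(n), function(i) {
    cl <- classes[i]
    switch(cl,
      inert = drug_model(labels[i], "none", concentration),
      tonic = drug_model(labels[i], "tonic", concentration,
                         kd_rest = jit(concentration * 4), tonic_tau = 300),
      slow_unbind = drug_model(labels[i], "state_dependent", concentration,
                               k_on = jit(1), k_off = jit(0.821)),
      fast_unbind = drug_model(labels[i], "state_dependent", concentration,
                               k_on = jit(3), k_off = jit(10)),
      gating_shift = drug_model(labels[i], "gating_shift", concentration,
                                inact_shift = -jit(15)))
  })
  names(models) <- labels
  tab <- data.frame(label = labels, class = classes,
                    concentration = concentration,
                    active = classes %in% c("slow_unbind", "fast_unbind"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, models = models), class = "drug_library")
}

#' @export
print.drug_library <- function(x, ...) {
  cat("Compound library:", nrow(x$table), "compounds\n")
  print(table(x$table$class))
  invisible(x)
}

.lookup_drug <- function(map, well, library) {
  row <- map[map$well == well, ]
  if (row$role == "negative_control" || is.na(row$compound)) return(NULL)
  if (row$role == "positive_control")
    return(drug_preset("amitriptyline", row$concentration_uM))
  library$models[[row$compound]]
}

#' Simulate every well of a plate
#'
#' Runs the membrane model and optical readout end-to-end for each
#' non-empty well: the well's compound model is applied to the reference
#' cell, the NaV conductance receives a per-well multiplicative jitter (8%
#' CV, emulating well-to-well biological variability in spike height), the
#' cell is stimulated with the screen protocol after a dark lead-in, and
#' the voltage is rendered as noisy indicator fluorescence.  Each well's
#' noise stream is seeded deterministically from `(seed, scan position)`,
#' so a fixed master seed reproduces the plate bit-for-bit.
#'
#' @param map A [build_plate_map()] result.
#' @param protocol Stimulus [light_protocol()]; default the screen stimulus
#'   (eight 20 ms pulses, 50 mW/cm^2, 10 Hz).
#' @param cell,sensor,conditions Model parameter objects.
#' @param seed Master integer seed.
#' @param lead_in_s Dark lead-in before the first pulse (s).
#' @param total_s Total recorded duration per well (s).
#' @param gnav_cv Coefficient of variation of the per-well NaV conductance
#'   jitter.
#' @return A named list of [fluorescence_trace()] objects (one per
#'   non-empty well).
#' @export
simulate_plate <- function(map, protocol = pulse_train(8, 20, 50, 10),
                           cell = default_cell(), sensor = sensor_params(),
                           conditions = ionic_conditions(), seed = 1,
                           lead_in_s = 0.5, total_s = 3, gnav_cv = 0.08) {
  library <- attr(map, "library")
  active <- map[map$role != "empty", ]
  active <- active[order(active$scan_order), ]
  lead_ms <- lead_in_s * 1000
  full <- light_protocol(c(lead_ms, protocol$segments$duration_ms),
                         c(0, protocol$segments$intensity),
                         label = protocol$label)
  full$stim_onsets <- protocol$stim_onsets + lead_ms
  traces <- vector("list", nrow(active))
  names(traces) <- active$well
  for (i in seq_len(nrow(active))) {
    w <- active$well[i]
    well_seed <- (as.integer(seed) * 1009L + active$scan_order[i]) %% 2147483629L
    set.seed(well_seed)
    cell_w <- cell
    cell_w$g_nav <- cell$g_nav * exp(rnorm(1, 0, gnav_cv))
    drug <- .lookup_drug(map, w, library)
    vt <- simulate_free(full, cell = cell_w, drug = drug,
                        conditions = conditions,
                        duration = total_s * 1000, record_dt = 0.1)
    traces[[i]] <- voltage_to_fluorescence(vt, sensor, seed = NULL,
                                           well_id = w)
  }
  traces
}

#' Analyse a plate of fluorescence traces
#'
#' The complete screen analysis: per-well photobleach correction, spike
#' extraction, the use-dependence index, amplitude SD, alternation score
#' and SNR; control statistics; the Z-prime factor computed on sigma; and
#' 5-SD hit calling.  Wells whose reference spike fails the detection floor
#' are flagged and excluded from control statistics and hit calling.
#'
#' @param traces Named list of [fluorescence_trace()] objects from
#'   [simulate_plate()] (or read from disk).
#' @param map The [build_plate_map()] used to generate them.
#' @param window_s Photobleach-correction window (s).
#' @param search_ms,baseline_ms,floor Spike-extraction settings
#'   (see [extract_spikes()]).
#' @return An object of class `screen_result`: list with `wells` (per-well
#'   metric table), `zprime`, `controls` (summary stats), `hit_threshold`
#'   and `n_hits`.
#' @export
run_screen <- function(traces, map, window_s = 1, search_ms = 80,
                       baseline_ms = 30, floor = 0.005) {
  missing_wells <- setdiff(map$well[map$role != "empty"], names(traces))
  if (length(missing_wells))
    warning("missing traces for wells: ",
            paste(missing_wells, collapse = ", "))
  rows <- lapply(names(traces), function(w) {
    tr <- traces[[w]]
    corr <- photobleach_correct(tr, window_s)
    st <- extract_spikes(corr, search_ms = search_ms,
                         baseline_ms = baseline_ms, floor = floor)
    snr <- tryCatch(compute_snr(corr, st, search_ms = search_ms),
                    error = function(e) NA_real_)
    data.frame(well = w,
               sigma = if (st$flagged) NA_real_ else amplitude_sd(st),
               gamma = if (st$flagged) NA_real_
                       else use_dependence_index(st),
               alternation = if (st$flagged) NA_real_
                             else alternation_score(st),
               spike_count = sum(st$S > floor),
               mean_dff = mean(st$S),
               snr = snr,
               flagged = st$flagged,
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  wells <- merge(map[, c("well", "compound", "concentration_uM", "role")],
                 wells, by = "well", sort = FALSE)
  wells <- wells[order(match(wells$well, map$well)), ]

  ok <- !wells$flagged & !is.na(wells$sigma)
  neg <- wells$sigma[ok & wells$role == "negative_control"]
  pos <- wells$sigma[ok & wells$role == "positive_control"]
  zp <- if (length(pos) >= 2 && length(neg) >= 2)
    zprime(pos, neg) else NA_real_
  hits <- rep(FALSE, nrow(wells))
  thr <- NA_real_
  if (length(neg) >= 4) {
    hits <- call_hits(wells$sigma, wells$role)
    thr <- attr(hits, "threshold")
  }
  wells$hit <- as.logical(hits)
  structure(list(wells = wells, zprime = zp,
                 controls = list(
                   neg_mean = mean(neg), neg_sd = stats::sd(neg),
                   pos_mean = mean(pos), pos_sd = stats::sd(pos),
                   n_neg = length(neg), n_pos = length(pos)),
                 hit_threshold = thr, n_hits = sum(wells$hit)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen result\n")
  cat(sprintf("  controls: sigma %.4f +/- %.4f (neg, n=%d) vs %.4f +/- %.4f (pos, n=%d)\n",
              x$controls$neg_mean, x$controls$neg_sd, x$controls$n_neg,
              x$controls$pos_mean, x$controls$pos_sd, x$controls$n_pos))
  cat(sprintf("  Z' (sigma) = %.3f\n", x$zprime))
  cat(sprintf("  hits: %d of %d test wells (threshold sigma > %.4f)\n",
              x$n_hits, sum(x$wells$role == "test"), x$hit_threshold))
  invisible(x)
}

#' @export
plot.screen_result <- function(x, ...) {
  w <- x$wells[!x$wells$flagged & !is.na(x$wells$sigma), ]
  cols <- c(negative_control = "forestgreen", positive_control = "red",
            test = "grey40")
  graphics::plot(w$sigma, w$gamma, col = cols[w$role],
                 pch = ifelse(w$hit, 17, 1),
                 xlab = expression(sigma), ylab = expression(Gamma), ...)
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 1,
                   bty = "n")
  invisible(x)
}

## ---- delimited-text serialisation --------------------------------------

#' Read and write plate maps, traces and screen reports
#'
#' All files are tab-separated text.  A plate map round-trips losslessly; a
#' fluorescence trace is stored as one row per frame (`well_id`, `time_s`,
#' `intensity`) with stimulus times in a `.stim` sidecar file, and
#' round-trips to within 1e-9.
#'
#' @param map A `plate_map`.
#' @param path Output path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_plate_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("well", "compound",
                                            "concentration_uM", "role")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  rows <- LETTERS[1:16]
  df$row <- substr(df$well, 1, 1)
  df$column <- as.integer(substring(df$well, 2))
  scanned <- df$column >= 2 & df$column <= 23
  df$scan_order <- NA_integer_
  df$scan_order[scanned] <- order(order(df$column[scanned],
                                        match(df$row[scanned], rows)))
  df <- df[, c("well", "row", "column", "compound", "concentration_uM",
               "role", "scan_order")]
  class(df) <- c("plate_map", "data.frame")
  df
}

#' @rdname write_plate_map
#' @param trace A [fluorescence_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(well_id = trace$well_id,
                   time_s = sprintf("%.9f", trace$times),
                   intensity = sprintf("%.15g", trace$F))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".stim")
  utils::write.table(data.frame(stim_time_s = sprintf("%.9f",
                                                      trace$stim_times)),
                     sidecar, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"))
  sidecar <- paste0(path, ".stim")
  stim <- if (file.exists(sidecar))
    utils::read.table(sidecar, header = TRUE, sep = "\t")$stim_time_s
  else numeric()
  fluorescence_trace(df$well_id[1], df$time_s, df$intensity,
                     stim_times = as.numeric(stim))
}

#' @rdname write_plate_map
#' @param result A `screen_result`.
#' @param dir Output directory (created if needed).
#' @export
write_screen_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$wells, file.path(dir, "well_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  qc <- data.frame(metric = c("zprime", "neg_mean_sigma", "neg_sd_sigma",
                              "pos_mean_sigma", "pos_sd_sigma",
                              "hit_threshold", "n_hits"),
                   value = c(result$zprime, result$controls$neg_mean,
                             result$controls$neg_sd, result$controls$pos_mean,
                             result$controls$pos_sd, result$hit_threshold,
                             result$n_hits))
  utils::write.table(qc, file.path(dir, "plate_qc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
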