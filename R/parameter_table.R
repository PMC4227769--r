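#' Commitment to catalysis from pulse-chase gel series
#'
#' Partitioning of the pre-formed enzyme-substrate complex is quantified by
#' comparing the product plateau reached in the presence of the chase
#' (complex formed first, then chased) against the plateau without chase,
#' after subtracting the baseline control in which chase and substrate are
#' added at the same time: `C = (plateau_chase - plateau_baseline) /
#' plateau_no_chase`, clipped to \[0, 1\]. Plateaus come from
#' single-exponential approach fits; a series whose fit does not saturate
#' within the observed window is rejected.
#'
#' @param chase data.frame (time, fraction product) with chase added after
#'   complex formation
#' @param no_chase matching series without chase
#' @param baseline optional simultaneous-addition control series; defaults
#'   to a zero baseline
#' @return list with `commitment`, the three plateaus, and the fits
#' @export
pulse_chase_commitment <- function(chase, no_chase, baseline = NULL) {
  plat <- function(series, label) {
    if (max(abs(series[[2L]])) < 1e-9) return(list(endpoint = 0, fit = NULL))
    f <- fit_single_turnover(series)
    if (!isTRUE(f$identifiable))
      stop("plateau not reached in ", label, " series (no saturation)")
    k <- f$k_obs
    if (max(series[[1L]]) * k < 1.5)
      stop("plateau not reached in ", label,
           " series: observation window shorter than ~1.5/k")
    list(endpoint = f$endpoint, fit = f)
  }
  pc <- plat(chase, "chase")
  pn <- plat(no_chase, "no-chase")
  pb <- if (is.null(baseline)) list(endpoint = 0, fit = NULL)
        else plat(baseline, "baseline")
  if (pn$endpoint <= 0) stop("no product formed in the no-chase control")
  C <- (pc$endpoint - pb$endpoint) / pn$endpoint
  list(commitment = min(max(C, 0), 1),
       plateau_chase = pc$endpoint, plateau_no_chase = pn$endpoint,
       plateau_baseline = pb$endpoint,
       fits = list(chase = pc$fit, no_chase = pn$fit, baseline = pb$fit))
}

#' A single measured quantity for the parameter table
#'
#' @param value point estimate
#' @param se standard error (NA if unknown)
#' @param limit `"none"` for a point value, `"lower"`/`"upper"` for a
#'   one-sided bound (quantities too fast or too slow to measure)
#' @return a `measurement` list
#' @export
measurement <- function(value, se = NA_real_,
                        limit = c("none", "lower", "upper")) {
  limit <- match.arg(limit)
  list(value = value, se = se, limit = limit)
}

as_measurement <- function(x) {
  if (is.list(x) && !is.null(x$value)) x else measurement(as.numeric(x)[1L])
}

#' Compile per-variant microscopic constants into a parameter table
#'
#' Takes per-variant, per-context stage outputs — measured `k_on`, `k_find`,
#' `k_2obs` (observed flip-phase rate), `k_unflip`, `k_chem` (s^-1; from
#' single-turnover fits in min^-1 divide by 60 first), `commitment`, `IC50`
#' — and compiles the report: `k_flip = k_2obs - k_unflip` (derived),
#' `K_flip = k_flip / k_unflip` (derived), `k_unflip` from a commitment when
#' no direct measurement exists (derived). Limits propagate as limits.
#' Every cell carries a provenance tag (`measured` / `derived` / `limit`).
#'
#' Duplicate measurements of the same cell are pooled by inverse variance,
#' unless they disagree by more than 3 combined standard deviations, which
#' raises a conflict error naming the cells. When both a direct `k_unflip`
#' and a commitment-implied value exist and differ by more than 10%, the
#' spread is flagged in the table's notes rather than silently averaged.
#'
#' @param fits a list of stage outputs; each element is a list with
#'   `variant`, `context`, and any of the quantities above, either bare
#'   numbers or [measurement()] objects
#' @param sig_figs significant figures for the `reported` column (rounded
#'   half away from zero, matching how such tables are printed)
#' @return an object of class `parameter_table` (a long-format data.frame
#'   with columns `variant`, `context`, `parameter`, `value`, `se`,
#'   `reported`, `provenance`, `note`)
#' @export
compile_parameter_table <- function(fits, sig_figs = 2) {
  params <- c("k_on", "k_find", "k_2obs", "k_flip", "k_unflip", "K_flip",
              "k_chem", "commitment", "IC50")
  rows <- list()
  if (length(fits)) {
    keys <- unique(vapply(fits, function(f)
      paste(f$variant, f$context, sep = "|"), character(1)))
    for (key in keys) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      group <- Filter(function(f)
        identical(paste(f$variant, f$context, sep = "|"), key), fits)
      cells <- list()
      for (f in group) for (p in intersect(names(f), params)) {
        m <- as_measurement(f[[p]])
        if (is.null(cells[[p]])) cells[[p]] <- list(m)
        else cells[[p]] <- c(cells[[p]], list(m))
      }
      cells <- lapply(stats::setNames(names(cells), names(cells)),
                      function(p) pool_cell(cells[[p]], parts[1L], p))
      rows <- c(rows, derive_cells(cells, parts[1L], parts[2L], sig_figs))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(0), context = character(0),
               parameter = character(0), value = numeric(0), se = numeric(0),
               reported = numeric(0), provenance = character(0),
               note = character(0))
  structure(df, class = c("parameter_table", "data.frame"))
}

pool_cell <- function(ms, variant, param) {
  if (length(ms) == 1L) return(ms[[1L]])
  vals <- vapply(ms, `[[`, numeric(1), "value")
  ses <- vapply(ms, `[[`, numeric(1), "se")
  comb_sd <- sqrt(sum(ses^2, na.rm = TRUE))
  if (comb_sd == 0) comb_sd <- 0.05 * mean(vals)  # fallback precision
  if (diff(range(vals)) > 3 * comb_sd)
    stop(sprintf("conflicting measurements for %s %s: %s (> 3 SD apart)",
                 variant, param, paste(signif(vals, 3), collapse = " vs ")))
  if (all(is.finite(ses)) && all(ses > 0)) {
    w <- 1 / ses^2
    measurement(sum(w * vals) / sum(w), sqrt(1 / sum(w)),
                ms[[1L]]$limit)
  } else measurement(mean(vals), stats::sd(vals) / sqrt(length(vals)),
                     ms[[1L]]$limit)
}

derive_cells <- function(cells, variant, context, sig_figs) {
  note_unflip <- ""
  # k_unflip: direct, else implied by commitment + k_chem
  implied <- NULL
  if (!is.null(cells$commitment) && !is.null(cells$k_chem) &&
      cells$commitment$value > 0)
    implied <- unflip_from_commitment(cells$k_chem$value,
                                      cells$commitment$value)
  if (is.null(cells$k_unflip) && !is.null(implied)) {
    cells$k_unflip <- measurement(implied)
    cells$k_unflip$provenance <- "derived"
  } else if (!is.null(cells$k_unflip) && !is.null(implied)) {
    spread <- abs(implied - cells$k_unflip$value) /
      max(cells$k_unflip$value, .Machine$double.eps)
    if (spread > 0.10)
      note_unflip <- sprintf(
        "direct %.3g vs commitment-implied %.3g s^-1 (%.0f%% spread)",
        cells$k_unflip$value, implied, 100 * spread)
  }
  # k_flip: direct measurement wins, else k_2obs - k_unflip
  if (is.null(cells$k_flip) && !is.null(cells$k_2obs) &&
      !is.null(cells$k_unflip)) {
    cells$k_flip <- measurement(
      derive_k_flip(cells$k_2obs$value, cells$k_unflip$value))
    cells$k_flip$provenance <- "derived"
  }
  if (is.null(cells$K_flip) && !is.null(cells$k_flip) &&
      !is.null(cells$k_unflip) && cells$k_unflip$value > 0) {
    cells$K_flip <- measurement(
      equilibrium_flip_constant(cells$k_flip$value, cells$k_unflip$value))
    cells$K_flip$provenance <- "derived"
  }
  lapply(stats::setNames(names(cells), names(cells)), function(p) {
    m <- cells[[p]]
    prov <- if (!is.null(m$provenance)) m$provenance
            else if (m$limit != "none") "limit" else "measured"
    data.frame(variant = variant, context = context, parameter = p,
               value = m$value, se = m$se,
               reported = signif_half_up(m$value, sig_figs),
               provenance = prov,
               note = if (p == "k_unflip") note_unflip else "",
               stringsAsFactors = FALSE)
  })
}

#' @export
print.parameter_table <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Parameter table (empty)\n")
    return(invisible(x))
  }
  cat("Kinetic parameters by variant\n")
  df <- as.data.frame(x)
  for (ctx in unique(df$context)) {
    sub <- df[df$context == ctx, ]
    wide <- stats::reshape(
      sub[, c("variant", "parameter", "reported")],
      idvar = "parameter", timevar = "variant", direction = "wide")
    names(wide) <- sub("^reported\\.", "", names(wide))
    cat("context:", ctx, "\n")
    print(wide, row.names = FALSE)
  }
  flagged <- df[df$note != "", ]
  if (nrow(flagged))
    for (i in seq_len(nrow(flagged)))
      cat(sprintf("note [%s %s %s]: %s\n", flagged$variant[i],
                  flagged$context[i], flagged$parameter[i], flagged$note[i]))
  invisible(x)
}

#' Export a parameter table to CSV, JSON and markdown
#'
#' @param table a `parameter_table`
#' @param path output path without extension
#' @param formats subset of `"csv"`, `"json"`, `"md"`
#' @return the written paths, invisibly
#' @export
export_parameter_table <- function(table, path,
                                   formats = c("csv", "json", "md")) {
  df <- as.data.frame(table)
  written <- character(0)
  if ("csv" %in% formats) {
    f <- paste0(path, ".csv")
    utils::write.csv(df, f, row.names = FALSE)
    written <- c(written, f)
  }
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(df, f, auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, f)
  }
  if ("md" %in% formats) {
    f <- paste0(path, ".md")
    lines <- c("| variant | context | parameter | value | reported | provenance |",
               "|---|---|---|---|---|---|",
               vapply(seq_len(nrow(df)), function(i)
                 sprintf("| %s | %s | %s | %.6g | %.6g | %s |",
                         df$variant[i], df$context[i], df$parameter[i],
                         df$value[i], df$reported[i], df$provenance[i]),
                 character(1)))
    writeLines(lines, f)
    written <- c(written, f)
  }
  invisible(written)
}
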