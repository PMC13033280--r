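#' File formats
#'
#' All interchange files are UTF-8 comma-delimited text with a one-line
#' header, decimal points, ISO-8601 timestamps and `#` comment lines for
#' object-level metadata (`# key: value`). Numeric fields round-trip
#' losslessly at 12 significant digits.
#'
#' Schemas:
#' \describe{
#'   \item{session}{columns `plaque_id, detector_id, direction, depth_mm,
#'     reading, acquisition_time_s, timestamp`; one row per reading;
#'     background rows have `depth_mm = "BG"` and direction `pre`/`post`;
#'     metadata `temperature_C`, `electrometer_factor`, `session_date`.}
#'   \item{curve}{columns `depth_mm, dose_rate, u_rel_k1, extrapolated`;
#'     metadata `source_id`, `origin`, `reference_time`.}
#'   \item{kq table}{columns `depth_mm, k_value`; metadata `plaque_model`,
#'     `quality_Q0`, `u_typeA_rel`, `u_typeB_rel` (one quality per file).}
#'   \item{certificate}{columns `depth_mm, dose_rate`; metadata `plaque_id`,
#'     `reference_time`, `u_rel_expanded`, `k_cov`.}
#'   \item{budget}{columns `name, utype, value_rel, depth_mm, group`
#'     (`depth_mm` empty for scalar components; repeated names with depths
#'     form a depth-indexed component).}
#'   \item{geometry chain}{columns `depth_mm, g1, g2, g3, g4, g5`.}
#' }
#'
#' @name rudose-io
NULL

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- ""
  out
}

# ---- generic delimited text with '# key: value' comments -----------------

write_commented_csv <- function(df, path, comments = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(comments))
    writeLines(sprintf("# %s: %s", k, comments[[k]]), con)
  # quote only the columns whose values contain delimiters
  needs_quote <- which(vapply(df, function(col) any(grepl('[",]', col)),
                              logical(1)))
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     quote = if (length(needs_quote)) needs_quote else FALSE)
}

read_commented_csv <- function(path, required_cols) {
  if (!file.exists(path)) abort_parse("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  comments <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) comments[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!is_comment]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) abort_parse("%s: no header line found", path)
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) abort_parse("%s: %s", path, conditionMessage(e)))
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0)
    abort_parse("%s: missing column(s) %s", path,
                paste(missing_cols, collapse = ", "))
  # map data row i to its physical line for error messages
  data_line <- which(!is_comment & nzchar(trimws(lines)))[-1]
  list(comments = comments, data = df, lines = data_line)
}

parse_num_col <- function(raw, col, path, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(raw$data[[col]]))
  bad <- is.na(out) & !(allow_na & !nzchar(trimws(raw$data[[col]])))
  if (any(bad))
    abort_parse("%s: line %d, column '%s': not a number ('%s')",
                path, raw$lines[which(bad)[1]], col,
                raw$data[[col]][which(bad)[1]])
  out
}

# ---- sessions ------------------------------------------------------------

#' Read and write measurement-session files
#'
#' One row per electrometer reading; rows sharing a direction and depth form
#' one reading series. See [rudose-io] for the schema.
#'
#' @param path file path.
#' @return `read_session()`: a [measurement_session()].
#' @export
read_session <- function(path) {
  cols <- c("plaque_id", "detector_id", "direction", "depth_mm",
            "reading", "acquisition_time_s", "timestamp")
  raw <- read_commented_csv(path, cols)
  df <- raw$data
  ok_dir <- df$direction %in% c("forward", "reverse", "pre", "post")
  if (!all(ok_dir))
    abort_parse("%s: line %d, column 'direction': invalid value '%s'",
                path, raw$lines[which(!ok_dir)[1]],
                df$direction[which(!ok_dir)[1]])
  is_bg <- toupper(df$depth_mm) == "BG"
  bad_bgdir <- is_bg & !(df$direction %in% c("pre", "post"))
  if (any(bad_bgdir))
    abort_parse("%s: line %d: background rows need direction pre/post",
                path, raw$lines[which(bad_bgdir)[1]])
  depth <- rep(NA_real_, nrow(df))
  if (any(!is_bg)) {
    sub <- raw
    sub$data <- df[!is_bg, , drop = FALSE]
    sub$lines <- raw$lines[!is_bg]
    depth[!is_bg] <- parse_num_col(sub, "depth_mm", path)
  }
  reading <- parse_num_col(raw, "reading", path)
  acq <- parse_num_col(raw, "acquisition_time_s", path)

  make_series <- function(idx, direction) {
    reading_series(depth_mm = depth[idx][1], readings = reading[idx],
                   acquisition_time_s = acq[idx][1],
                   timestamp = df$timestamp[idx][1], direction = direction)
  }
  series_for <- function(direction) {
    sel <- which(df$direction == direction & !is_bg)
    if (length(sel) == 0)
      abort_parse("%s: no %s reading rows", path, direction)
    lapply(split(sel, depth[sel]), make_series, direction = direction)
  }
  bg_for <- function(direction) {
    sel <- which(df$direction == direction & is_bg)
    if (length(sel) == 0)
      abort_parse("%s: missing %s background rows", path, direction)
    make_series(sel, direction)
  }
  cm <- raw$comments
  measurement_session(
    forward = unname(series_for("forward")),
    reverse = unname(series_for("reverse")),
    bg_pre = bg_for("pre"), bg_post = bg_for("post"),
    temperature_C = as.numeric(cm[["temperature_C"]] %||% 20),
    electrometer_factor = as.numeric(cm[["electrometer_factor"]] %||% 1),
    detector_id = df$detector_id[1], plaque_id = df$plaque_id[1],
    session_date = cm[["session_date"]] %||% df$timestamp[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_session
#' @param session a [measurement_session()].
#' @export
write_session <- function(session, path) {
  row_block <- function(s) {
    data.frame(plaque_id = session$plaque_id,
               detector_id = session$detector_id,
               direction = s$direction,
               depth_mm = if (is.na(s$depth_mm)) "BG" else fmt_num(s$depth_mm),
               reading = fmt_num(s$readings),
               acquisition_time_s = fmt_num(s$acquisition_time_s),
               timestamp = format_timestamp(s$timestamp))
  }
  all_series <- c(list(session$bg_pre), session$forward, session$reverse,
                  list(session$bg_post))
  df <- do.call(rbind, lapply(all_series, row_block))
  write_commented_csv(df, path, list(
    temperature_C = fmt_num(session$temperature_C),
    electrometer_factor = fmt_num(session$electrometer_factor),
    session_date = format_timestamp(session$session_date)))
  invisible(path)
}

# ---- curves --------------------------------------------------------------

#' Read and write depth-dose curve files
#'
#' @param path file path.
#' @return `read_curve()`: a [depth_dose_curve()].
#' @export
read_curve <- function(path) {
  raw <- read_commented_csv(path, c("depth_mm", "dose_rate", "u_rel_k1"))
  cm <- raw$comments
  u <- parse_num_col(raw, "u_rel_k1", path, allow_na = TRUE)
  extra <- if ("extrapolated" %in% names(raw$data))
    raw$data$extrapolated %in% c("TRUE", "true", "1")
  else rep(FALSE, nrow(raw$data))
  depth_dose_curve(
    depths_mm = parse_num_col(raw, "depth_mm", path),
    dose_rate = parse_num_col(raw, "dose_rate", path),
    reference_time = cm[["reference_time"]] %||% "1970-01-01",
    u_rel_k1 = u,
    source_id = cm[["source_id"]] %||% "",
    origin = cm[["origin"]] %||% "synthetic",
    extrapolated = extra)
}

#' @rdname read_curve
#' @param curve a [depth_dose_curve()].
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(depth_mm = fmt_num(curve$depths_mm),
                   dose_rate = fmt_num(curve$dose_rate),
                   u_rel_k1 = fmt_num(curve$u_rel_k1),
                   extrapolated = curve$extrapolated)
  write_commented_csv(df, path, list(
    source_id = curve$source_id, origin = curve$origin,
    reference_time = format_timestamp(curve$reference_time)))
  invisible(path)
}

# ---- kq tables -----------------------------------------------------------

#' Read and write beam-quality correction tables
#'
#' One (plaque model, calibration quality) pair per file; see [rudose-io].
#'
#' @param path file path.
#' @return `read_kq_table()`: a [kq_table()].
#' @export
read_kq_table <- function(path) {
  raw <- read_commented_csv(path, c("depth_mm", "k_value"))
  cm <- raw$comments
  if (is.null(cm[["quality_Q0"]]))
    abort_parse("%s: missing '# quality_Q0:' metadata", path)
  kq_table(plaque_model = cm[["plaque_model"]] %||% "CCB",
           quality = cm[["quality_Q0"]],
           depth_mm = parse_num_col(raw, "depth_mm", path),
           k_value = parse_num_col(raw, "k_value", path),
           u_typeA_rel = as.numeric(cm[["u_typeA_rel"]] %||% 0),
           u_typeB_rel = as.numeric(cm[["u_typeB_rel"]] %||% 0))
}

#' @rdname read_kq_table
#' @param table a [kq_table()].
#' @export
write_kq_table <- function(table, path) {
  df <- data.frame(depth_mm = fmt_num(table$depth_mm),
                   k_value = fmt_num(table$k_value))
  write_commented_csv(df, path, list(
    plaque_model = table$plaque_model,
    quality_Q0 = table$quality_pair[["Q0"]],
    u_typeA_rel = fmt_num(table$u_typeA_rel),
    u_typeB_rel = fmt_num(table$u_typeB_rel)))
  invisible(path)
}

# ---- certificates --------------------------------------------------------

#' Read and write vendor certificate files
#'
#' @param path file path.
#' @return `read_certificate()`: a [certificate()].
#' @export
read_certificate <- function(path) {
  raw <- read_commented_csv(path, c("depth_mm", "dose_rate"))
  cm <- raw$comments
  certificate(plaque_id = cm[["plaque_id"]] %||% "",
              reference_time = cm[["reference_time"]] %||% "1970-01-01",
              depth_mm = parse_num_col(raw, "depth_mm", path),
              dose_rate = parse_num_col(raw, "dose_rate", path),
              u_rel_expanded = as.numeric(cm[["u_rel_expanded"]] %||% 11),
              k_cov = as.numeric(cm[["k_cov"]] %||% 2))
}

#' @rdname read_certificate
#' @param cert a [certificate()].
#' @export
write_certificate <- function(cert, path) {
  df <- data.frame(depth_mm = fmt_num(cert$depth_mm),
                   dose_rate = fmt_num(cert$dose_rate))
  write_commented_csv(df, path, list(
    plaque_id = cert$plaque_id,
    reference_time = format_timestamp(cert$reference_time),
    u_rel_expanded = fmt_num(cert$u_rel_expanded),
    k_cov = fmt_num(cert$k_cov)))
  invisible(path)
}

# ---- budgets -------------------------------------------------------------

#' Read and write uncertainty-budget files
#'
#' Columns `name, utype, value_rel[, depth_mm][, group]`; repeated names
#' with depths form a depth-indexed component.
#'
#' @param path file path.
#' @param groups optional character vector: keep only components whose
#'   `group` is among these.
#' @return `read_budget()`: an [uncertainty_budget()].
#' @export
read_budget <- function(path, groups = NULL) {
  raw <- read_commented_csv(path, c("name", "utype", "value_rel"))
  df <- raw$data
  ok_ut <- df$utype %in% c("A", "B")
  if (!all(ok_ut))
    abort_parse("%s: line %d, column 'utype': must be A or B (got '%s')",
                path, raw$lines[which(!ok_ut)[1]], df$utype[which(!ok_ut)[1]])
  value <- parse_num_col(raw, "value_rel", path)
  depth <- if ("depth_mm" %in% names(df))
    suppressWarnings(as.numeric(df$depth_mm)) else rep(NA_real_, nrow(df))
  grp <- if ("group" %in% names(df)) df$group else rep("", nrow(df))
  if (!is.null(groups)) {
    keep <- grp %in% groups
    check_that(any(keep), "no budget components in group(s) %s",
               paste(groups, collapse = ", "))
    df <- df[keep, , drop = FALSE]; value <- value[keep]
    depth <- depth[keep]; grp <- grp[keep]
  }
  comps <- lapply(unique(df$name), function(nm) {
    sel <- df$name == nm
    d <- depth[sel]
    if (all(is.na(d)))
      uncertainty_component(nm, df$utype[sel][1], value[sel][1],
                            group = grp[sel][1])
    else {
      o <- order(d)
      uncertainty_component(nm, df$utype[sel][1], value[sel][o],
                            depth_mm = d[o], group = grp[sel][1])
    }
  })
  uncertainty_budget(comps, description = raw$comments[["description"]] %||%
                       basename(path))
}

#' @rdname read_budget
#' @param budget an [uncertainty_budget()].
#' @export
write_budget <- function(budget, path) {
  rows <- lapply(budget$components, function(comp) {
    n <- length(comp$value_rel)
    data.frame(name = comp$name, utype = comp$utype,
               value_rel = fmt_num(comp$value_rel),
               depth_mm = if (is.null(comp$depth_mm)) rep("", n)
               else fmt_num(comp$depth_mm),
               group = comp$group)
  })
  write_commented_csv(do.call(rbind, rows), path,
                      list(description = budget$description))
  invisible(path)
}

# ---- geometry chains -----------------------------------------------------

#' Read and write geometry-dose chain files
#'
#' @param path file path.
#' @return `read_chain()`: a [geometry_dose_chain()].
#' @export
read_chain <- function(path) {
  cols <- c("depth_mm", "g1", "g2", "g3", "g4", "g5")
  raw <- read_commented_csv(path, cols)
  vals <- lapply(cols, function(col) parse_num_col(raw, col, path))
  names(vals) <- cols
  do.call(geometry_dose_chain, vals)
}

#' @rdname read_chain
#' @param chain a [geometry_dose_chain()].
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(depth_mm = fmt_num(chain$depth_mm),
                   g1 = fmt_num(chain$g1), g2 = fmt_num(chain$g2),
                   g3 = fmt_num(chain$g3), g4 = fmt_num(chain$g4),
                   g5 = fmt_num(chain$g5))
  write_commented_csv(df, path, list())
  invisible(path)
}

# ---- packaged fixtures ---------------------------------------------------

rudose_extdata <- function(file) {
  p <- system.file("extdata", file, package = "rudose")
  if (!nzchar(p)) abort_parse("packaged data file '%s' not found", file)
  p
}

#' Packaged CCB beam-quality correction table
#'
#' Depth-dependent k_Q,Q0 factors for CCB plaque measurements with a
#' microSilicon diode calibrated in Co-60 or a 6 MeV electron beam, 2-10 mm
#' in 1 mm steps. Valid only for CCB plaques under the measurement setup the
#' factors were computed for.
#'
#' @param quality calibration quality, `"Co60"` or `"6MeV"`.
#' @return a [kq_table()].
#' @export
ccb_kq_table <- function(quality = c("Co60", "6MeV")) {
  quality <- match.arg(quality)
  read_kq_table(rudose_extdata(
    if (quality == "Co60") "kq_ccb_co60.csv" else "kq_ccb_6mev.csv"))
}

#' Packaged uncertainty budgets
#'
#' `alanine_budget()`: the seven-component budget for absorbed dose to water
#' measured with alanine (Co-60-traceable), with the depth-dependent setup
#' repeatability / alanine variability component tabulated at 2-5 mm.
#'
#' `diode_budget()`: the budget for diode measurements. The Ru-106
#' measurement components and the traceability components form separate
#' groups; the caller selects the traceability chain (Co-60 or 6 MeV) and
#' whether measurement components are included. The depth-dependent
#' measurement repeatability (0.3-0.8 %) is tabulated at its depth extremes
#' (2 and 10 mm) with linear interpolation between.
#'
#' @return an [uncertainty_budget()].
#' @export
alanine_budget <- function() {
  read_budget(rudose_extdata("budget_alanine.csv"))
}

#' @rdname alanine_budget
#' @param traceability which calibration chain to include, `"Co60"` or
#'   `"6MeV"`.
#' @param include_measurement include the Ru-106 measurement components.
#' @export
diode_budget <- function(traceability = c("Co60", "6MeV"),
                         include_measurement = TRUE) {
  traceability <- match.arg(traceability)
  groups <- paste0("traceability_", tolower(traceability))
  if (include_measurement) groups <- c("ru106_measurement", groups)
  read_budget(rudose_extdata("budget_diode.csv"), groups = groups)
}
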