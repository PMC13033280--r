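#' Uncertainty components and budgets
#'
#' GUM-style uncertainty bookkeeping: each component is a relative standard
#' uncertainty in percent, typed A (statistical) or B (other means), either a
#' scalar or a depth-indexed table. Components are treated as uncorrelated
#' and combine in quadrature to a combined standard uncertainty at k = 1.
#'
#' Depth-indexed components interpolate linearly between their tabulated
#' depths and never extrapolate: evaluating outside the tabulated range is a
#' range error.
#'
#' @param name component label, unique within a budget.
#' @param utype `"A"` or `"B"`.
#' @param value_rel relative standard uncertainty in percent; a scalar, or a
#'   vector parallel to `depth_mm` for a depth-dependent component.
#' @param depth_mm optional strictly increasing depths (mm) indexing
#'   `value_rel`.
#' @param group optional grouping label (e.g. a traceability chain), used to
#'   select subsets of a budget file.
#' @return an object of class `uncertainty_component`.
#' @examples
#' uncertainty_component("N_D,w (Co60)", "B", 0.5)
#' uncertainty_component("Measurement repeatability", "A",
#'                       c(0.3, 0.8), depth_mm = c(2, 10))
#' @export
uncertainty_component <- function(name, utype = c("A", "B"), value_rel,
                                  depth_mm = NULL, group = "") {
  utype <- match.arg(utype)
  check_that(is.character(name) && nzchar(name), "component needs a name")
  check_that(all(value_rel >= 0), "value_rel must be >= 0")
  if (!is.null(depth_mm)) {
    check_that(length(depth_mm) == length(value_rel),
               "depth_mm and value_rel must be parallel")
    check_that(all(diff(depth_mm) > 0),
               "component depths must strictly increase")
  } else {
    check_that(length(value_rel) == 1L,
               "a scalar component has exactly one value")
  }
  structure(list(name = name, utype = utype,
                 value_rel = as.numeric(value_rel),
                 depth_mm = if (is.null(depth_mm)) NULL else as.numeric(depth_mm),
                 group = group),
            class = "uncertainty_component")
}

#' @rdname uncertainty_component
#' @param components list of [uncertainty_component()] with unique names.
#' @param description budget label.
#' @return `uncertainty_budget()`: an object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(components, description = "") {
  check_that(length(components) >= 1L, "budget needs at least one component")
  check_that(all(vapply(components, inherits, logical(1),
                        "uncertainty_component")),
             "all budget entries must be uncertainty_component objects")
  nm <- vapply(components, `[[`, character(1), "name")
  check_that(!anyDuplicated(nm), "component names must be unique")
  structure(list(components = components, description = description),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget '%s' (%d components)\n",
              x$description, length(x$components)))
  for (comp in x$components) {
    v <- if (is.null(comp$depth_mm))
      sprintf("%g", comp$value_rel)
    else
      paste(sprintf("%g (%g mm)", comp$value_rel, comp$depth_mm),
            collapse = ", ")
    cat(sprintf("  [%s] %-45s %s %%\n", comp$utype, comp$name, v))
  }
  invisible(x)
}

# Evaluate one component at a depth; scalar components ignore depth.
component_value_at <- function(comp, depth_mm = NULL) {
  if (is.null(comp$depth_mm)) return(comp$value_rel)
  if (is.null(depth_mm))
    abort_validation("component '%s' is depth-indexed; depth_mm is required",
                     comp$name)
  rng <- range(comp$depth_mm)
  if (depth_mm < rng[1] || depth_mm > rng[2])
    abort_range("depth %g mm outside component '%s' coverage [%g, %g] mm",
                depth_mm, comp$name, rng[1], rng[2])
  if (length(comp$depth_mm) == 1L) return(comp$value_rel)
  stats::approx(comp$depth_mm, comp$value_rel, xout = depth_mm)$y
}

#' Combine an uncertainty budget in quadrature
#'
#' Evaluates every component (depth-dependent ones at `depth_mm`) and returns
#' the combined relative standard uncertainty at coverage factor k = 1,
#' `sqrt(sum(u_i^2))`. `depth_mm` is required exactly when some component is
#' depth-indexed, and must lie within every such component's tabulated range.
#'
#' @param budget an [uncertainty_budget()].
#' @param depth_mm evaluation depth, mm (optional for all-scalar budgets).
#' @return combined relative standard uncertainty, percent (k = 1).
#' @examples
#' b <- uncertainty_budget(list(
#'   uncertainty_component("a", "A", 3),
#'   uncertainty_component("b", "B", 4)))
#' combine_budget(b)  # 5
#' @export
combine_budget <- function(budget, depth_mm = NULL) {
  check_that(inherits(budget, "uncertainty_budget"),
             "combine_budget needs an uncertainty_budget")
  vals <- vapply(budget$components, component_value_at, numeric(1),
                 depth_mm = depth_mm)
  sqrt(sum(vals^2))
}

#' Expand a standard uncertainty by a coverage factor
#'
#' @param u_k1 combined standard uncertainty, percent, at k = 1.
#' @param k_cov coverage factor (>= 1; k = 2 is approximately 95 % coverage).
#' @return expanded uncertainty, percent.
#' @export
expand_uncertainty <- function(u_k1, k_cov) {
  check_that(all(u_k1 >= 0), "u_k1 must be >= 0")
  check_that(all(k_cov >= 1), "coverage factor must be >= 1")
  k_cov * u_k1
}

#' Round an uncertainty for report output
#'
#' Round-half-even to a number of significant figures, the convention used
#' for printed budget tables.
#'
#' @param u uncertainty value(s), percent.
#' @param sig_figs significant figures to keep (>= 1).
#' @return rounded value(s).
#' @export
round_budget <- function(u, sig_figs = 2) {
  check_that(sig_figs >= 1, "sig_figs must be >= 1")
  signif(u, sig_figs)
}
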