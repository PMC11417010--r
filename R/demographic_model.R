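#' Demographic models in genetic units
#'
#' A demographic model is an ordered list of epochs, oldest to newest, sitting
#' on top of an implicit ancestral population at its reference size. All
#' quantities are in the conventional "genetic" units of diffusion-based SFS
#' software: population sizes `nu` are ratios to the ancestral reference size
#' \eqn{N_e^{anc}}, epoch durations `T` are in units of \eqn{2 N_e^{anc}}
#' generations, and migration rates are \eqn{M = 2 N_e^{anc} m} where `m` is
#' the per-generation fraction of the *receiving* population replaced by
#' migrants. `M_1to2` moves genes, forward in time, from deme 1 into deme 2.
#'
#' A model may contain at most one split: all single-deme epochs must precede
#' all two-deme epochs, and the split happens at the boundary. A model with no
#' two-deme epoch describes a single panmictic population (any two "demes"
#' sampled from it are arbitrary labels).
#'
#' @param T epoch duration (> 0), units of `2 Ne_anc` generations.
#' @param nu size(s) at the *end* of the epoch, relative to `Ne_anc`; length 1
#'   for a single-deme epoch, length 2 for a post-split epoch.
#' @param dynamics `"sudden"`, `"linear"` or `"exponential"`; recycled across
#'   demes. Sudden means the population sits at `nu` throughout the epoch;
#'   linear/exponential interpolate from the size inherited at the epoch start.
#' @param M_1to2,M_2to1 scaled migration rates (two-deme epochs only).
#' @return `epoch()` returns a list describing one epoch; `demographic_model()`
#'   a validated object of class `"demographic_model"`.
#' @examples
#' # one split, one epoch, asymmetric migration
#' m <- demographic_model(list(
#'   epoch(T = 0.2, nu = c(2, 5), M_1to2 = 1.5, M_2to1 = 0)
#' ))
#' @export
epoch <- function(T, nu, dynamics = "sudden", M_1to2 = 0, M_2to1 = 0) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0,
            is.numeric(nu), length(nu) %in% 1:2, all(nu > 0),
            M_1to2 >= 0, M_2to1 >= 0)
  dynamics <- rep_len(dynamics, length(nu))
  ok <- dynamics %in% c("sudden", "linear", "exponential")
  if (!all(ok)) stop("dynamics must be 'sudden', 'linear' or 'exponential'")
  list(T = T, nu = nu, dynamics = dynamics, M_1to2 = M_1to2, M_2to1 = M_2to1)
}

#' @rdname epoch
#' @param epochs list of [epoch()] objects, oldest first.
#' @param name optional model name.
#' @export
demographic_model <- function(epochs = list(), name = NULL) {
  ndeme <- vapply(epochs, function(e) length(e$nu), 1L)
  if (length(ndeme) > 1L && any(diff(ndeme) < 0))
    stop("single-deme epochs must precede two-deme epochs (at most one split)")
  for (e in epochs) {
    if (length(e$nu) == 1L && (e$M_1to2 > 0 || e$M_2to1 > 0))
      stop("migration is only meaningful in two-deme epochs")
  }
  structure(list(epochs = epochs, name = name,
                 split = if (any(ndeme == 2L)) which(ndeme == 2L)[1L] else NA_integer_),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>", if (!is.null(x$name)) x$name else "", "\n")
  if (!length(x$epochs)) cat("  equilibrium (standard neutral)\n")
  for (k in seq_along(x$epochs)) {
    e <- x$epochs[[k]]
    cat(sprintf("  epoch %d%s: T=%.4g nu=(%s) dyn=(%s) M12=%.3g M21=%.3g\n",
                k, if (!is.na(x$split) && x$split == k) " [split]" else "",
                e$T, paste(signif(e$nu, 4), collapse = ","),
                paste(substr(e$dynamics, 1, 3), collapse = ","),
                e$M_1to2, e$M_2to1))
  }
  invisible(x)
}

dyn_code <- function(d) match(d, c("sudden", "linear", "exponential")) - 1L

# Encode a model as the numeric epoch matrix shared with the C++ cores.
# Start sizes carry the inherited size for interpolating dynamics; at the
# split both daughters inherit the ancestral end size.
epoch_matrix <- function(model) {
  eps <- model$epochs
  m <- matrix(0, nrow = length(eps), ncol = 10)
  colnames(m) <- c("T", "ndemes", "nu1_start", "nu1_end", "dyn1",
                   "nu2_start", "nu2_end", "dyn2", "M_1to2", "M_2to1")
  prev <- c(1, 1) # size(s) at end of previous epoch (ancestral reference = 1)
  for (k in seq_along(eps)) {
    e <- eps[[k]]
    nd <- length(e$nu)
    m[k, "T"] <- e$T
    m[k, "ndemes"] <- nd
    m[k, "nu1_start"] <- prev[1]
    m[k, "nu1_end"] <- e$nu[1]
    m[k, "dyn1"] <- dyn_code(e$dynamics[1])
    if (nd == 2L) {
      m[k, "nu2_start"] <- prev[2]
      m[k, "nu2_end"] <- e$nu[2]
      m[k, "dyn2"] <- dyn_code(e$dynamics[2])
      m[k, "M_1to2"] <- e$M_1to2
      m[k, "M_2to1"] <- e$M_2to1
    } else {
      m[k, c("nu2_start", "nu2_end")] <- 1
    }
    prev <- if (nd == 2L) e$nu else c(e$nu, e$nu) # split inherits ancestral size
  }
  m
}

has_split <- function(model) !is.na(model$split)

#' Catalog of two-population demographic model structures
#'
#' The fixed catalog compared by median-AIC model selection: three panmictic
#' (no-split) structures differing in the number of size-change epochs, four
#' isolation-with-migration structures differing in an extra ancestral epoch
#' and in whether migration is symmetric, plus `gadma_best`, the structure
#' found by the genetic-algorithm search on the bonnethead shark data
#' (ancestral sudden growth, split, linear growth in deme 1, sudden growth in
#' deme 2, one-way gene flow from deme 1 to deme 2).
#'
#' Each entry carries the free parameter names, log10-scale search bounds, a
#' `build(par)` closure returning the [demographic_model()], and the AIC
#' parameter count `k` (free parameters plus the profiled theta).
#'
#' @param names optional subset of model names.
#' @return named list of catalog entries.
#' @export
model_catalog <- function(names = NULL) {
  cat_ <- list(
    sc1ns = list(
      description = "No split, one epoch",
      params = character(0),
      build = function(par) demographic_model(list(), name = "sc1ns")
    ),
    sc2ns = list(
      description = "No split, two epochs",
      params = c("nu", "T"),
      build = function(par) demographic_model(list(
        epoch(T = par[["T"]], nu = par[["nu"]])), name = "sc2ns")
    ),
    sc3ns = list(
      description = "No split, three epochs",
      params = c("nu1", "T1", "nu2", "T2"),
      build = function(par) demographic_model(list(
        epoch(T = par[["T1"]], nu = par[["nu1"]]),
        epoch(T = par[["T2"]], nu = par[["nu2"]])), name = "sc3ns")
    ),
    s2m = list(
      description = "One split, one epoch with asymmetric migration",
      params = c("nu1", "nu2", "T", "M12", "M21"),
      build = function(par) demographic_model(list(
        epoch(T = par[["T"]], nu = c(par[["nu1"]], par[["nu2"]]),
              M_1to2 = par[["M12"]], M_2to1 = par[["M21"]])), name = "s2m")
    ),
    s2msm = list(
      description = "One split, one epoch with symmetric migration",
      params = c("nu1", "nu2", "T", "M"),
      build = function(par) demographic_model(list(
        epoch(T = par[["T"]], nu = c(par[["nu1"]], par[["nu2"]]),
              M_1to2 = par[["M"]], M_2to1 = par[["M"]])), name = "s2msm")
    ),
    sc2el = list(
      description = "One split, two epochs with asymmetric migration",
      params = c("nuA", "TA", "nu1", "nu2", "T", "M12", "M21"),
      build = function(par) demographic_model(list(
        epoch(T = par[["TA"]], nu = par[["nuA"]]),
        epoch(T = par[["T"]], nu = c(par[["nu1"]], par[["nu2"]]),
              M_1to2 = par[["M12"]], M_2to1 = par[["M21"]])), name = "sc2el")
    ),
    sc2elsm = list(
      description = "One split, two epochs with symmetric migration",
      params = c("nuA", "TA", "nu1", "nu2", "T", "M"),
      build = function(par) demographic_model(list(
        epoch(T = par[["TA"]], nu = par[["nuA"]]),
        epoch(T = par[["T"]], nu = c(par[["nu1"]], par[["nu2"]]),
              M_1to2 = par[["M"]], M_2to1 = par[["M"]])), name = "sc2elsm")
    ),
    gadma_best = list(
      description = paste("Ancestral sudden growth, split, linear growth in",
                          "deme 1, sudden growth in deme 2, one-way 1->2 flow"),
      params = c("nuA", "TA", "nu1", "nu2", "T", "M12"),
      build = function(par) demographic_model(list(
        epoch(T = par[["TA"]], nu = par[["nuA"]]),
        epoch(T = par[["T"]], nu = c(par[["nu1"]], par[["nu2"]]),
              dynamics = c("linear", "sudden"),
              M_1to2 = par[["M12"]], M_2to1 = 0)),
        name = "gadma_best")
    )
  )
  for (nm in names(cat_)) {
    cat_[[nm]]$name <- nm
    cat_[[nm]]$bounds <- default_bounds(nm, cat_[[nm]]$params)
    cat_[[nm]]$k <- length(cat_[[nm]]$params) + 1L # + profiled theta
  }
  if (!is.null(names)) {
    bad <- setdiff(names, base::names(cat_))
    if (length(bad)) stop("unknown model name(s): ", paste(bad, collapse = ", "))
    cat_ <- cat_[names]
  }
  cat_
}

#' Default search bounds for a catalog entry
#'
#' Log-scale boxes used by the multi-start optimizer: size ratios
#' `nu` in `[1e-3, 1e3]`, times `T` in `[1e-4, 5]` (units of `2 Ne_anc`
#' generations), scaled migration `M` in `[~0, 50]` (the lower edge is a
#' numerically-zero 1e-3 so that rates can be searched on the log scale).
#'
#' @param name catalog entry name (only used for error messages).
#' @param params character vector of free-parameter names.
#' @return list with `lower` and `upper` named numeric vectors.
#' @export
default_bounds <- function(name, params = NULL) {
  if (is.null(params)) {
    entry <- model_catalog()[[name]]
    if (is.null(entry)) stop("unknown model name: ", name)
    return(entry$bounds)
  }
  kind <- substr(params, 1, 1)
  lower <- ifelse(kind == "n", 1e-3, ifelse(kind == "T", 1e-4, 1e-3))
  upper <- ifelse(kind == "n", 1e3, ifelse(kind == "T", 5, 50))
  list(lower = setNames(lower, params), upper = setNames(upper, params))
}
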