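#' Read and write demographic models as YAML
#'
#' A model file holds `name` and a list of `epochs`, each with `T`, `nu`
#' (length 1 or 2), `dynamics`, and optional `M_1to2` / `M_2to1` — the same
#' fields as [epoch()]. Round-trips through [demographic_model()].
#'
#' @param model a [demographic_model()].
#' @param path file path.
#' @return `model_from_yaml()` returns a [demographic_model()].
#' @export
model_to_yaml <- function(model, path) {
  eps <- lapply(model$epochs, function(e)
    list(T = e$T, nu = e$nu, dynamics = e$dynamics,
         M_1to2 = e$M_1to2, M_2to1 = e$M_2to1))
  yaml::write_yaml(list(name = model$name, epochs = eps), path)
  invisible(path)
}

#' @rdname model_to_yaml
#' @export
model_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  eps <- lapply(y$epochs, function(e)
    epoch(T = e$T, nu = unlist(e$nu),
          dynamics = if (is.null(e$dynamics)) "sudden" else unlist(e$dynamics),
          M_1to2 = if (is.null(e$M_1to2)) 0 else e$M_1to2,
          M_2to1 = if (is.null(e$M_2to1)) 0 else e$M_2to1))
  demographic_model(eps, name = y$name)
}
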