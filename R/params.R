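#' @useDynLib odftoolbox, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median rnorm runif sd aov TukeyHSD
#'   complete.cases residuals
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom graphics plot
NULL

.odf_env <- new.env(parent = emptyenv())

#' Packaged film and scenario parameters
#'
#' Returns the packaged parameter set describing the four films (C1, C2:
#' sodium carboxymethylcellulose; P1, P2: polyvinyl alcohol), their
#' disintegration endpoints per method, oral-cavity-model event archetypes,
#' BioTribometer friction signatures and kinematics, and video rendering
#' defaults. All scenario onsets and magnitudes live in a single editable
#' JSON file (`extdata/scenario-params.json`) rather than in code.
#'
#' @return A nested list mirroring the JSON parameter file.
#' @export
odf_params <- function() {
  if (is.null(.odf_env$params)) {
    path <- system.file("extdata", "scenario-params.json",
                        package = "odftoolbox", mustWork = TRUE)
    .odf_env$params <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .odf_env$params
}

#' Film identifiers known to the packaged parameter set
#' @return Character vector of film ids.
#' @export
film_ids <- function() names(odf_params()$films)

#' Methods known to the packaged parameter set
#' @return Character vector: `"petri"`, `"ocm"`, `"btm"`.
#' @export
odf_methods <- function() c("petri", "ocm", "btm")

#' Film specification
#'
#' Static description of one packaged orodispersible film: polymer type,
#' molecular weight, stock-solution concentration, printed dimensions
#' (nominal 30 x 20 mm) and measured thickness.
#'
#' @param film_id One of `"C1"`, `"C2"`, `"P1"`, `"P2"`.
#' @return A `film_spec` list with fields `film_id`, `polymer`, `mw_kda`,
#'   `conc_pct_wv`, `width_mm`, `height_mm`, `thickness_um`.
#' @export
film_spec <- function(film_id) {
  p <- odf_params()
  if (!is.character(film_id) || length(film_id) != 1L ||
      !film_id %in% names(p$films)) {
    stop("unknown film_id '", paste(film_id, collapse = ","),
         "'; expected one of: ", paste(names(p$films), collapse = ", "))
  }
  spec <- c(list(film_id = film_id), as.list(p$films[[film_id]]))
  stopifnot(spec$width_mm > 0, spec$height_mm > 0, spec$thickness_um > 0)
  structure(spec, class = "film_spec")
}

#' @export
print.film_spec <- function(x, ...) {
  cat(sprintf("<film_spec %s: %s %g kDa, %g%% w/v, %g x %g mm, %g um>\n",
              x$film_id, x$polymer, x$mw_kda, x$conc_pct_wv,
              x$width_mm, x$height_mm, x$thickness_um))
  invisible(x)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  v <- ((as.numeric(seed) %% 65521) * 31907 + k * 7919 + 13) %% 2147483647
  as.integer(v)
}
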