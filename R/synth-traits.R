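#' Specify a synthetic trait table
#'
#' Defines per-trait means, standard deviations and target Pearson
#' correlations with canopy temperature.  Traits are generated by a
#' linear-Gaussian construction: each trait is `mean + sd * (r * z_ct +
#' sqrt(1 - r^2) * e)` with `z_ct` the standardised CT and `e`
#' independent standard normal noise, so the population correlation with
#' CT is exactly the target `r`.  Because every trait loads on the single
#' CT factor with independent residuals, the implied joint covariance is
#' positive semidefinite for any targets in `[-1, 1]`; targets outside
#' that range are rejected at construction.
#'
#' @param traits Data frame with columns `trait` (name), `mean`, `sd`
#'   (trait units) and `r_ct` (target Pearson correlation with CT, in
#'   `[-1, 1]`).
#' @param seed Integer seed.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(traits, seed = 1L) {
  traits <- as.data.frame(traits)
  need <- c("trait", "mean", "sd", "r_ct")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    stop("trait spec lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(traits$r_ct) > 1)) {
    stop("correlation targets must lie in [-1, 1]", call. = FALSE)
  }
  if (any(traits$sd < 0)) stop("trait sd must be >= 0", call. = FALSE)
  structure(list(traits = traits, seed = as.integer(seed)),
            class = "trait_spec")
}

#' Generate a trait table correlated with CT
#'
#' @param spec A [trait_spec()].
#' @param ct Data frame with at least `line` and a CT column (`rel_ct` or
#'   `ct_mean`), one row per observational unit; traits are generated per
#'   row.
#' @return `ct` with one additional numeric column per trait.
#' @export
make_trait_table <- function(spec, ct) {
  stopifnot(inherits(spec, "trait_spec"))
  ct <- as.data.frame(ct)
  if (nrow(ct) == 0L) stop("CT table is empty", call. = FALSE)
  ctcol <- intersect(c("rel_ct", "ct_mean"), names(ct))[1]
  if (is.na(ctcol)) stop("no CT column (`rel_ct` or `ct_mean`) in `ct`",
                         call. = FALSE)
  z <- ct[[ctcol]]
  if (stats::sd(z) == 0) {
    stop("CT has zero variance; cannot induce correlation", call. = FALSE)
  }
  z <- (z - mean(z)) / stats::sd(z)
  n <- length(z)
  tt <- spec$traits
  out <- ct
  withr::with_seed(spec$seed, {
    for (i in seq_len(nrow(tt))) {
      r <- tt$r_ct[i]
      e <- stats::rnorm(n)
      out[[tt$trait[i]]] <- tt$mean[i] +
        tt$sd[i] * (r * z + sqrt(1 - r^2) * e)
    }
  })
  out
}
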