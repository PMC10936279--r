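#' Build a 1-D scatterer phantom inside the Doppler gate
#'
#' Draws point scatterers uniformly over the gate span (extended by `margin`
#' on each side so motion does not immediately carry scatterers out of the
#' simulated region) with standard-normal reflectivities. The phantom stands
#' in for muscle tissue speckle along the scan line.
#'
#' @param params An [acquisition_params()] object.
#' @param density Scatterers per mm of (extended) gate span; must be > 0.
#' @param seed Integer seed; the phantom is reproducible from it.
#' @param margin Extension beyond each gate boundary, mm.
#' @return An object of class `phantom` with fields `scatterer_depths` (mm),
#'   `reflectivities`, `seed`, `margin`.
#' @examples
#' ph <- build_phantom(acquisition_params(), density = 10, seed = 1)
#' length(ph$scatterer_depths)
#' @export
build_phantom <- function(params, density = 10, seed = 1L, margin = 2) {
  stopifnot(inherits(params, "acquisition_params"))
  if (!is.numeric(density) || density <= 0) {
    abort("`density` must be a positive number of scatterers per mm.",
          class = "twitchtdi_invalid_argument")
  }
  lo <- params$gate_upper - margin
  hi <- params$gate_lower + margin
  span <- hi - lo
  if (span <= 0) {
    abort("empty gate span.", class = "twitchtdi_invalid_argument")
  }
  n <- as.integer(round(density * span))
  depths <- withr_seed(seed, {
    d <- sort(runif(n, lo, hi))
    a <- rnorm(n)
    list(d = d, a = a)
  })
  structure(
    list(scatterer_depths = depths$d,
         reflectivities = depths$a,
         seed = as.integer(seed),
         margin = margin),
    class = "phantom"
  )
}

# evaluate expr with a local, restored RNG state seeded from `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
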