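#' Construct a stain matrix
#'
#' A stain matrix holds one optical-density direction per stain, one row per
#' stain over the (R, G, B) channels. Rows are normalized to unit Euclidean
#' length. Stains mix additively in optical-density space (Beer-Lambert), so
#' per-pixel stain concentrations are recovered by inverting this matrix
#' ([deconvolve()]).
#'
#' @param hematoxylin,dab,residual numeric length-3 OD direction vectors
#'   (non-negative). `residual` defaults to the complement direction
#'   `sqrt(1 - h^2 - d^2)` per channel, the usual construction when only two
#'   chromogens are physically present.
#' @return A 3x3 numeric matrix of class `stain_matrix` with rows
#'   `hematoxylin`, `dab`, `residual` and columns `R`, `G`, `B`.
#' @seealso [default_hdab_stain_matrix()], [deconvolve()]
#' @export
stain_matrix <- function(hematoxylin, dab, residual = NULL) {
  norm1 <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || !all(is.finite(v))) {
      stop("each stain vector must be 3 finite numbers", call. = FALSE)
    }
    if (any(v < 0)) stop("stain vector components must be non-negative", call. = FALSE)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be non-zero", call. = FALSE)
    v / n
  }
  h <- norm1(hematoxylin)
  d <- norm1(dab)
  if (is.null(residual)) {
    r <- sqrt(pmax(0, 1 - h^2 - d^2))
    if (all(r == 0)) stop("residual complement is degenerate", call. = FALSE)
    r <- r / sqrt(sum(r^2))
  } else {
    r <- norm1(residual)
  }
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  sv <- svd(m)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 1e6) {
    stop("stain matrix is ill-conditioned (condition number >= 1e6)", call. = FALSE)
  }
  class(m) <- c("stain_matrix", "matrix")
  m
}

#' Conventional hematoxylin/DAB stain matrix
#'
#' The standard published optical-density vectors for hematoxylin and DAB
#' (the values in ubiquitous use for brightfield H-DAB deconvolution), with
#' the residual row built as the per-channel complement. Deterministic.
#'
#' @return A `stain_matrix`.
#' @examples
#' m <- default_hdab_stain_matrix()
#' rowSums(m^2)  # each row has unit norm
#' @export
default_hdab_stain_matrix <- function() {
  stain_matrix(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.268, 0.570, 0.776)
  )
}

# columns-as-stains system matrix: od = A %*% conc
stain_system_matrix <- function(stains) {
  stopifnot(inherits(stains, "stain_matrix"))
  t(unclass(stains))
}
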