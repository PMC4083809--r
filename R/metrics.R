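#' Segmentation overlap and distance metrics
#'
#' Dice `2|A∩B| / (|A|+|B|)`, Jaccard `|A∩B| / |A∪B|` (both defined as 1
#' when both masks are empty), the symmetric Hausdorff distance between the
#' mask boundaries (in pixels; `Inf` if exactly one mask is empty), and the
#' count of disagreeing pixels.
#'
#' @param a,b Logical (or 0/1) matrices of the same shape.
#' @return `dice()`, `jaccard()`, `hausdorff_distance()`: a scalar.
#'   `seg_score()`: a one-row tibble with columns `dice`, `jaccard`,
#'   `hausdorff`, `changed_pixels`.
#' @examples
#' a <- matrix(FALSE, 8, 8); a[3:4, 3:4] <- TRUE
#' b <- matrix(FALSE, 8, 8); b[3:4, 4:5] <- TRUE
#' dice(a, b)   # 0.5
#' seg_score(a, b)
#' @name seg_metrics
NULL

check_masks <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("masks must be matrices of the same shape", call. = FALSE)
  }
  list(a = a != 0, b = b != 0)
}

#' @rdname seg_metrics
#' @export
dice <- function(a, b) {
  m <- check_masks(a, b)
  sa <- sum(m$a); sb <- sum(m$b)
  if (sa + sb == 0) return(1)
  2 * sum(m$a & m$b) / (sa + sb)
}

#' @rdname seg_metrics
#' @export
jaccard <- function(a, b) {
  m <- check_masks(a, b)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

boundary_coords <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(i, lim) pmin(pmax(i, 1L), lim)
  interior <- m &
    m[pad(0:(nr - 1), nr), ] & m[pad(2:(nr + 1), nr), ] &
    m[, pad(0:(nc - 1), nc)] & m[, pad(2:(nc + 1), nc)]
  which(m & !interior, arr.ind = TRUE)
}

#' @rdname seg_metrics
#' @export
hausdorff_distance <- function(a, b) {
  m <- check_masks(a, b)
  ea <- !any(m$a); eb <- !any(m$b)
  if (ea && eb) return(0)
  if (ea || eb) return(Inf)
  pa <- boundary_coords(m$a)
  pb <- boundary_coords(m$b)
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

#' @rdname seg_metrics
#' @export
seg_score <- function(a, b) {
  j <- jaccard(a, b)
  tibble::tibble(
    dice = 2 * j / (1 + j),
    jaccard = j,
    hausdorff = hausdorff_distance(a, b),
    changed_pixels = sum((a != 0) != (b != 0))
  )
}

#' Count 4-connected foreground components
#'
#' Simple flood-fill labelling of a binary mask; used to check that a
#' converged segmentation has no small noise-induced components.
#'
#' @param mask Logical matrix.
#' @return Integer vector of component sizes (decreasing); empty if the mask
#'   is empty.
#' @export
component_sizes <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  nxt <- 0L
  idx <- which(m & lab == 0L)
  while (length(idx) > 0) {
    nxt <- nxt + 1L
    stack <- idx[1]
    lab[stack] <- nxt
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (i > 1) p - 1L, if (i < nr) p + 1L,
                  if (j > 1) p - nr, if (j < nc) p + nr)) {
        if (m[q] && lab[q] == 0L) {
          lab[q] <- nxt
          stack <- c(stack, q)
        }
      }
    }
    sizes <- c(sizes, size)
    idx <- which(m & lab == 0L)
  }
  sort(sizes, decreasing = TRUE)
}
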