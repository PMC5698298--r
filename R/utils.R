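# Internal helpers shared across modules.

#' Derive a child seed from a base seed and an index
#'
#' All stochastic stages draw their randomness from one user-supplied integer
#' seed; per-molecule / per-frame streams are split off deterministically so
#' that regenerating molecule i does not depend on how many draws molecule
#' i-1 consumed.  Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed integer base seed
#' @param index non-negative integer stream index
#' @return an integer seed (always below 2^31)
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 30269 + 1
  as.integer(s %% 2147483647)
}

# Run expr with a temporary RNG state seeded from `seed`; restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`;
# out[i, j] == m[i + dr, j + dc] where defined.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L - dr):min(nr, nr - dr)
  c_dst <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L) return(out)
  out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  out
}

# Separable Gaussian blur with edge replication.
gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(x) {
    # x filtered along columns; replicate-pad rows
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x, x[rep(nrow(x), r), , drop = FALSE])
    f <- stats::filter(xp, k, sides = 2)
    f[(r + 1L):(r + nrow(x)), , drop = FALSE]
  }
  m2 <- conv1(m)
  t(conv1(t(m2)))
}

# Bilinear interpolation of matrix heights at physical coordinates (x, y) nm.
# Pixel (row i, col j) has center ((j - 0.5) * px, (i - 0.5) * px) relative to
# the image origin. Points outside are clamped to the border.
interp_bilinear <- function(heights, x, y, pixel_size_nm, origin_nm = c(0, 0)) {
  nr <- nrow(heights); nc <- ncol(heights)
  cx <- (x - origin_nm[1]) / pixel_size_nm + 0.5
  cy <- (y - origin_nm[2]) / pixel_size_nm + 0.5
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  j0 <- pmin(floor(cx), nc - 1L); i0 <- pmin(floor(cy), nr - 1L)
  fx <- cx - j0; fy <- cy - i0
  h00 <- heights[cbind(i0, j0)]
  h01 <- heights[cbind(i0, j0 + 1L)]
  h10 <- heights[cbind(i0 + 1L, j0)]
  h11 <- heights[cbind(i0 + 1L, j0 + 1L)]
  h00 * (1 - fx) * (1 - fy) + h01 * fx * (1 - fy) +
    h10 * (1 - fx) * fy + h11 * fx * fy
}

# 8-connected component labelling of a logical mask via igraph.
# Returns an integer matrix (0 = background, components numbered 1..K by
# decreasing size).
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- seq_along(idx)
  lookup <- integer(length(mask)); lookup[idx] <- pos
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= ncol(mask)
    nidx <- (nj - 1L) * nr + ni
    ok[ok] <- mask[nidx[ok]]
    if (any(ok)) edges[[length(edges) + 1L]] <- rbind(pos[ok], lookup[nidx[ok]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  lab[idx] <- relabel[comp$membership]
  lab
}

# Resample a polyline (n x 2) at regular arc spacing; returns matrix of points
# including both endpoints.
resample_path <- function(path, step) {
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(path[1, , drop = FALSE])
  t_new <- unique(c(seq(0, L, by = step), L))
  x <- stats::approx(s, path[, 1], xout = t_new)$y
  y <- stats::approx(s, path[, 2], xout = t_new)$y
  cbind(x, y)
}

# Arc-length positions along a polyline.
path_arclength <- function(path) {
  c(0, cumsum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)))
}

# Interpolate the point at arc position s along a polyline.
point_at_arc <- function(path, s) {
  arc <- path_arclength(path)
  s <- pmin(pmax(s, 0), arc[length(arc)])
  cbind(stats::approx(arc, path[, 1], xout = s)$y,
        stats::approx(arc, path[, 2], xout = s)$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
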