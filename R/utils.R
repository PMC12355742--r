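#' @useDynLib neurofuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
#' @importFrom utils read.csv write.csv head modifyList
NULL

sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

#' Stable MD5 fingerprint of any R object
#'
#' Used for split-plan hashes, parameter-group freeze checks and run
#' manifests. Serializes with version 3 and hashes the bytes, so two objects
#' hash equal iff they are bit-identical after serialization.
#'
#' @param x Any serializable R object.
#' @return A 32-character hexadecimal string.
#' @export
nf_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

# Zero-pad the three spatial axes of a (D,H,W,C,B) array by p voxels each side.
pad5d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3] + 2 * p, d[4], d[5]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ] <- x
  out
}

unpad5d <- function(x, p, d_orig) {
  if (p == 0) return(x)
  x[p + seq_len(d_orig[1]), p + seq_len(d_orig[2]), p + seq_len(d_orig[3]), , ,
    drop = FALSE]
}

# (D,H,W,C,B) -> (S*B) x C matrix with rows ordered spatial-fastest then batch.
chan_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 3, 5, 4))
  dim(m) <- c(d[1] * d[2] * d[3] * d[5], d[4])
  m
}

# Inverse of chan_mat given the target (D,H,W,C,B) dims.
chan_unmat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[3], d[5], d[4])
  aperm(m, c(1, 2, 3, 5, 4))
}

# Ensure a 3-D array (adds unit axes for vectors/matrices passed by tests).
as_vol <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1, 1)
  x
}

#' Trilinear or nearest-neighbour resampling of a 3-D array
#'
#' Voxel-centre convention: target centre t maps to source coordinate
#' (t + 0.5) * (n_src / n_tgt) - 0.5 on each axis, clamped to the grid.
#' Nearest mode picks the closest source voxel, so binary masks stay binary.
#'
#' @param x 3-D numeric array.
#' @param target_shape Integer vector of length 3.
#' @param mode "trilinear" or "nearest".
#' @return A 3-D array with dim `target_shape`.
#' @export
resample_array <- function(x, target_shape, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  src <- dim(x)
  stopifnot(length(src) == 3, length(target_shape) == 3)
  coord <- lapply(1:3, function(a) {
    (seq_len(target_shape[a]) - 0.5) * (src[a] / target_shape[a]) - 0.5
  })
  if (mode == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(coord[[a]]) + 1, 1), src[a]))
    return(x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(coord[[a]]), 0), src[a] - 1))
  fr <- lapply(1:3, function(a) pmin(pmax(coord[[a]] - lo[[a]], 0), 1))
  i0 <- lapply(1:3, function(a) lo[[a]] + 1)
  i1 <- lapply(1:3, function(a) pmin(lo[[a]] + 2, src[a]))
  g <- function(ia, ib, ic) x[ia, ib, ic, drop = FALSE]
  w <- function(a, hi) if (hi) fr[[a]] else 1 - fr[[a]]
  out <- array(0, target_shape)
  for (bd in 0:1) for (bh in 0:1) for (bw in 0:1) {
    ia <- if (bd) i1[[1]] else i0[[1]]
    ib <- if (bh) i1[[2]] else i0[[2]]
    ic <- if (bw) i1[[3]] else i0[[3]]
    wt <- outer(outer(w(1, bd), w(2, bh)), w(3, bw))
    out <- out + wt * g(ia, ib, ic)
  }
  out
}

# Sample (ddof = 1) standard deviation, NA-safe length check.
sd1 <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
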