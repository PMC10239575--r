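# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Canonical unordered-edge representation: integer matrix, 2 columns,
# each row sorted i < j, rows deduplicated and ordered.
normalize_edges <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (anyNA(edges)) stop("edge list contains non-integer or missing ids")
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  e
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")

# Angle at vertex k between rays k->i and k->j, in degrees.
angle_at <- function(pk, pi_, pj) {
  u <- pi_ - pk
  v <- pj - pk
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate angle: coincident points")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

bbox_diagonal <- function(coords) {
  sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
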