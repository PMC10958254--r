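# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A binary raster is a logical matrix (or a numeric matrix of exactly 0/1).
.as_binary_matrix <- function(m, what = "mask") {
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  if (is.logical(m)) {
    if (anyNA(m)) stop(what, " contains NA", call. = FALSE)
    return(m)
  }
  v <- unique(as.vector(m))
  if (anyNA(v) || !all(v %in% c(0, 1))) {
    stop(what, " is not binary: values outside {0,1}", call. = FALSE)
  }
  mode(m) <- "logical"
  m
}

.check_same_dim <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " differ in shape: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic per-unit sub-seeds from one root seed, independent of the
# order units are processed in.
.split_seeds <- function(root_seed, n) {
  if (n == 0L) return(integer(0))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(root_seed %% 2147483646L))
  sample.int(2147483646L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

.rbind_rows <- function(lst) {
  if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
  else data.frame()
}

# Integer-pixel translation with zero fill. dr/dc > 0 move content toward
# larger row/column indices.
.shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dr) >= nr || abs(dc) >= nc) {
    stop("translation of (", dr, ", ", dc, ") px moves the raster off-grid",
         call. = FALSE)
  }
  out <- matrix(FALSE, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

# Boundary of a foreground set under 4-connectivity: foreground pixels with
# at least one 4-neighbour (or the raster edge) outside the set.
.boundary4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  core & !nb
}
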