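#' 4D BOLD time-series container
#'
#' Wraps a 4D array (x, y, z, t) together with its repetition time and voxel
#' size. The grid-to-world transform is the diagonal scaling by `voxel_size_mm`
#' with a zero origin at voxel (1,1,1); world coordinates of reports are
#' computed with [voxel_to_world()].
#'
#' @param data numeric 4D array, dimensions (x, y, z, t).
#' @param tr_s repetition time in seconds (> 0).
#' @param voxel_size_mm per-axis voxel size in mm (length 1 or 3).
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, tr_s, voxel_size_mm = 3) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("time dimension must have at least 2 volumes")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("`tr_s` must be > 0")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d grid, %d volumes, TR = %g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' @export
dim.bold4d <- function(x) dim(x$data)

n_timepoints <- function(bold) dim(bold$data)[4]
grid_dim <- function(bold) dim(bold$data)[1:3]

#' 3D metric map container
#'
#' A scalar map on the analysis grid tied to a gray-matter mask. `kind` records
#' what the values are: raw ReHo or DC, their mask-mean normalized versions
#' (`mReHo`, `mDC`), or a post-minus-pre `change` map.
#'
#' @param values numeric 3D array.
#' @param kind one of `"ReHo"`, `"mReHo"`, `"DC"`, `"mDC"`, `"change"`,
#'   `"weight"`, `"other"`.
#' @param mask logical 3D array, same dimensions as `values`.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @param provenance optional list recording the source session and parameters.
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(values, kind, mask, voxel_size_mm = 3,
                       provenance = list()) {
  kind <- match.arg(kind, c("ReHo", "mReHo", "DC", "mDC", "change",
                            "weight", "other"))
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` dimensions differ")
  if (!all(is.finite(values[mask])))
    stop("metric values inside the mask must be finite")
  values[!mask] <- 0
  if (kind == "ReHo" && any(values[mask] < -1e-9 | values[mask] > 1 + 1e-9))
    stop("ReHo values must lie in [0, 1]")
  if (kind == "DC" && any(values[mask] < -1e-9))
    stop("DC values must be nonnegative")
  structure(list(values = values, kind = kind, mask = mask,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 provenance = provenance),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map:%s> %s grid, %d mask voxels, mask mean %.4g\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              sum(x$mask), mean(x$values[x$mask])))
  invisible(x)
}

#' Voxelwise statistic map (F or t)
#'
#' @param values numeric 3D array of statistic values.
#' @param df degrees of freedom: length 2 `(df1, df2)` for F, length 1 for t.
#' @param mask logical 3D array.
#' @param stat `"F"` or `"t"`.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, df, mask, stat = c("F", "t"), voxel_size_mm = 3) {
  stat <- match.arg(stat)
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` dimensions differ")
  if (any(df <= 0)) stop("degrees of freedom must be positive")
  if (stat == "F" && length(df) != 2L) stop("F maps need df = (df1, df2)")
  if (stat == "F" && any(values[mask] < -1e-9, na.rm = TRUE))
    stop("F values must be nonnegative")
  structure(list(values = values, df = df, mask = mask, stat = stat,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map:%s> df = (%s), max = %.3f\n", x$stat,
              paste(x$df, collapse = ", "),
              suppressWarnings(max(x$values[x$mask], na.rm = TRUE))))
  invisible(x)
}

#' Voxelwise p-values of a statistic map
#'
#' Upper-tail p for F maps; two-tailed p for t maps.
#'
#' @param smap a [stat_map()].
#' @return 3D array of p-values (1 outside the mask).
#' @export
stat_p_values <- function(smap) {
  p <- array(1, dim(smap$values))
  v <- smap$values[smap$mask]
  if (smap$stat == "F") {
    pv <- stats::pf(v, smap$df[1], smap$df[2], lower.tail = FALSE)
  } else {
    pv <- 2 * stats::pt(abs(v), smap$df[1], lower.tail = FALSE)
  }
  p[smap$mask] <- pv
  p
}

# --- voxel/world coordinate helpers ------------------------------------------

#' Convert voxel indices (1-based) to world mm coordinates
#'
#' The synthetic grid uses a diagonal affine: world = (index - 1) * voxel size.
#'
#' @param idx integer vector of length 3, or an n x 3 matrix.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @return numeric vector or matrix of mm coordinates.
#' @export
voxel_to_world <- function(idx, voxel_size_mm = 3) {
  vs <- rep_len(voxel_size_mm, 3L)
  if (is.matrix(idx)) sweep(idx - 1, 2L, vs, `*`) else (idx - 1) * vs
}

#' @rdname voxel_to_world
#' @param mm world coordinate(s) in mm.
#' @export
world_to_voxel <- function(mm, voxel_size_mm = 3) {
  vs <- rep_len(voxel_size_mm, 3L)
  if (is.matrix(mm)) round(sweep(mm, 2L, vs, `/`)) + 1 else round(mm / vs) + 1
}

# linear index <-> (i,j,k) for a given 3D dim
index_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_index <- function(ijk, dims) {
  (ijk[, 3] - 1L) * dims[1] * dims[2] + (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
}

# flatten a bold4d to a t x V matrix (V in array order)
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4]))
}

# rebuild a bold4d from a t x V matrix given a template bold
matrix_bold <- function(m, template) {
  d <- dim(template$data)
  stopifnot(ncol(m) == prod(d[1:3]))
  bold4d(array(t(m), dim = c(d[1:3], nrow(m))), template$tr_s,
         template$voxel_size_mm)
}

# seed the RNG for the calling function only: the caller's RNG state is
# restored when that function exits, so seeded helpers do not clobber the
# session's random stream
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  }, envir = envir)
  set.seed(seed)
}
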