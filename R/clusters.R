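# Connected-component labeling on a 3D logical array.
# connectivity: 6 (faces), 18 (+edges) or 26 (+corners).
label_clusters <- function(mask, connectivity = 6) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  base <- neighborhood_offsets(27)
  ord <- rowSums(abs(base))
  offs <- switch(as.character(connectivity),
                 "6"  = base[ord == 1, , drop = FALSE],
                 "18" = base[ord >= 1 & ord <= 2, , drop = FALSE],
                 "26" = base[ord >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26"))
  lab <- array(0L, d)
  todo <- which(mask)
  nextlab <- 0L
  for (seed_vox in todo) {
    if (lab[seed_vox] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed_vox] <- nextlab
    frontier <- seed_vox
    while (length(frontier) > 0L) {
      ijk <- index_to_ijk(frontier, d)
      nb <- vector("list", nrow(offs))
      for (o in seq_len(nrow(offs))) {
        cand <- sweep(ijk, 2L, offs[o, ], `+`)
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
        nb[[o]] <- ijk_to_index(cand[ok, , drop = FALSE], d)
      }
      nb <- unique(unlist(nb))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab
}

# one-voxel dilation of a logical 3D array (face connectivity)
dilate_mask <- function(mask, connectivity = 6) {
  base <- neighborhood_offsets(27)
  ord <- rowSums(abs(base))
  offs <- switch(as.character(connectivity),
                 "6"  = base[ord <= 1, , drop = FALSE],
                 "26" = base,
                 stop("connectivity must be 6 or 26"))
  acc <- array(0, dim(mask))
  m <- array(as.numeric(mask), dim(mask))
  for (o in seq_len(nrow(offs))) acc <- acc + shift3d(m, offs[o, ])
  acc > 0
}

# keep only the largest connected component of a logical 3D array
largest_component <- function(mask, connectivity = 6) {
  lab <- label_clusters(mask, connectivity)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
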