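# Internal 3D binary morphology on logical arrays, 6-connectivity
# (face neighbours). Implemented with vectorised axis shifts; adequate for
# the phantom/volume sizes this package targets.

shift3d <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (axis == 1L) {
    out[dst, , ] <- x[src, , ]
  } else if (axis == 2L) {
    out[, dst, ] <- x[, src, ]
  } else {
    out[, , dst] <- x[, , src]
  }
  out
}

dilate6 <- function(x) {
  out <- x
  for (ax in 1:3) {
    out <- out | shift3d(x, ax, 1L) | shift3d(x, ax, -1L)
  }
  out
}

erode6 <- function(x) !dilate6(!x)

closing6 <- function(x) erode6(dilate6(x))

# grow `seed` inside `mask` to its full connected component (flood fill)
flood_component <- function(seed, mask) {
  comp <- seed & mask
  repeat {
    grown <- dilate6(comp) & mask
    if (sum(grown) == sum(comp)) return(comp)
    comp <- grown
  }
}

# largest 6-connected component of a logical array
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- -1L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood_component(seed, remaining)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  best
}

# fill interior cavities: background voxels unreachable from the array border
fill_holes <- function(mask) {
  bg <- !mask
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood_component(border & bg, bg)
  mask | (bg & !outside)
}
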