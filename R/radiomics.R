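# Compact radiomic feature catalog and extraction.
#
# Texture matrices are computed from grey levels discretized at a fixed bin
# width (default 25 HU, re-anchored at the ROI minimum so the features are
# invariant to constant intensity shifts). Pairwise/texture interactions are
# evaluated in-plane (within slices) and accumulated across all slices of
# the ROI; per-offset features (GLCM, GLRLM) are averaged over the four
# in-plane directions.

#' Built-in radiomic feature catalog
#'
#' A compact, documented catalog spanning the seven feature families: shape,
#' first-order, and the GLCM, GLRLM, GLSZM, GLDM and NGTDM texture matrices.
#' The catalog order is stable and configuration-independent; families can
#' be switched off for speed.
#'
#' @param families character vector of families to include (default: all 7).
#' @param bin_width grey-level discretization bin width in HU (default 25).
#' @return data.frame with columns `name` and `family`, attribute
#'   `bin_width`; the row order defines the feature order of
#'   [extract_radiomic_features()].
#' @export
feature_catalog <- function(families = c("shape", "firstorder", "GLCM",
                                         "GLRLM", "GLSZM", "GLDM", "NGTDM"),
                            bin_width = 25) {
  all_feats <- list(
    shape = c("voxel_count", "volume", "surface_area", "surface_to_volume",
              "sphericity", "compactness1", "compactness2",
              "spherical_disproportion", "max_3d_diameter",
              "max_2d_diameter_slice", "major_axis_length",
              "minor_axis_length", "least_axis_length", "elongation",
              "flatness"),
    firstorder = c("energy", "total_energy", "entropy", "minimum",
                   "p10", "p90", "maximum", "mean", "median", "iqr",
                   "range", "mad", "rmad", "rms", "skewness", "kurtosis",
                   "variance", "uniformity"),
    GLCM = c("contrast", "dissimilarity", "idm", "id", "asm",
             "joint_entropy", "correlation", "cluster_shade",
             "cluster_prominence"),
    GLRLM = c("sre", "lre", "gln", "rln", "run_percentage",
              "grey_level_variance"),
    GLSZM = c("sae", "lae", "gln", "zsn", "zone_percentage",
              "zone_entropy"),
    GLDM = c("sde", "lde", "gln", "dn", "dependence_entropy"),
    NGTDM = c("coarseness", "contrast", "busyness", "complexity", "strength")
  )
  bad <- setdiff(families, names(all_feats))
  if (length(bad)) {
    stop("unknown feature family: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  families <- names(all_feats)[names(all_feats) %in% families]
  cat_df <- do.call(rbind, lapply(families, function(f) {
    data.frame(name = paste0(tolower(f), "_", all_feats[[f]]),
               family = f, stringsAsFactors = FALSE)
  }))
  rownames(cat_df) <- NULL
  attr(cat_df, "bin_width") <- bin_width
  cat_df
}

# Discretize HU values into 1-based grey levels with a fixed bin width,
# re-anchored at the ROI minimum (constant-shift invariant).
discretize_intensities <- function(x, bin_width) {
  lv <- floor((x - min(x)) / bin_width) + 1L
  storage.mode(lv) <- "integer"
  lv
}

#' Extract radiomic features for one ROI
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] aligned with `volume`.
#' @param catalog a [feature_catalog()].
#' @return named numeric vector ordered as the catalog, with attributes
#'   `families` (family tag per feature) and `source` (the mask kind).
#' @export
extract_radiomic_features <- function(volume, mask,
                                      catalog = feature_catalog()) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$intensities), dim(mask$mask))) {
    stop("volume and mask shapes differ", call. = FALSE)
  }
  bw <- attr(catalog, "bin_width")
  vox <- volume$intensities[mask$mask]
  lv_arr <- array(NA_integer_, dim = dim(mask$mask))
  lv_arr[mask$mask] <- discretize_intensities(vox, bw)
  ng <- max(lv_arr, na.rm = TRUE)
  fams <- unique(catalog$family)
  vals <- list()
  if ("shape" %in% fams) {
    vals$shape <- shape_features(mask$mask, volume$spacing)
  }
  if ("firstorder" %in% fams) {
    vals$firstorder <- firstorder_features(vox, lv_arr[mask$mask],
                                           prod(volume$spacing))
  }
  if ("GLCM" %in% fams) vals$GLCM <- glcm_features(lv_arr, ng)
  if ("GLRLM" %in% fams) vals$GLRLM <- glrlm_features(lv_arr, ng)
  if ("GLSZM" %in% fams) vals$GLSZM <- glszm_features(lv_arr, ng)
  if ("GLDM" %in% fams) vals$GLDM <- gldm_features(lv_arr, ng)
  if ("NGTDM" %in% fams) vals$NGTDM <- ngtdm_features(lv_arr, ng)
  out <- numeric(nrow(catalog))
  names(out) <- catalog$name
  for (i in seq_len(nrow(catalog))) {
    fam <- catalog$family[i]
    short <- sub(paste0("^", tolower(fam), "_"), "", catalog$name[i])
    out[i] <- vals[[fam]][[short]]
  }
  if (any(!is.finite(out))) out[!is.finite(out)] <- 0
  attr(out, "families") <- catalog$family
  attr(out, "source") <- mask$kind
  out
}

## ---- shape ------------------------------------------------------------

shape_features <- function(m, spacing) {
  vox_vol <- prod(spacing)
  n_vox <- sum(m)
  volume <- n_vox * vox_vol
  area <- mesh_surface_area(m, spacing)
  idx <- which(m, arr.ind = TRUE)
  phys <- sweep(idx, 2L, spacing, `*`)
  # principal axes from the physical-coordinate covariance
  if (n_vox > 1L) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  # max 3D diameter over boundary voxels only
  bnd <- boundary_coords(m, spacing)
  max3d <- max_pairwise_distance(bnd)
  # max in-plane diameter on any single slice
  max2d <- 0
  for (s in unique(idx[, 1L])) {
    pts <- phys[idx[, 1L] == s, 2:3, drop = FALSE]
    if (nrow(pts) > 1L) max2d <- max(max2d, max_pairwise_distance(pts))
  }
  sph <- (36 * pi * volume^2)^(1 / 3) / area
  list(voxel_count = n_vox, volume = volume, surface_area = area,
       surface_to_volume = area / volume, sphericity = sph,
       compactness1 = volume / (sqrt(pi) * area^1.5),
       compactness2 = 36 * pi * volume^2 / area^3,
       spherical_disproportion = 1 / sph,
       max_3d_diameter = max3d, max_2d_diameter_slice = max2d,
       major_axis_length = axes[1L], minor_axis_length = axes[2L],
       least_axis_length = axes[3L],
       elongation = if (ev[1L] > 0) sqrt(ev[2L] / ev[1L]) else 0,
       flatness = if (ev[1L] > 0) sqrt(ev[3L] / ev[1L]) else 0)
}

boundary_coords <- function(m, spacing) {
  d <- dim(m)
  interior <- array(FALSE, d)
  if (all(d >= 3L)) {
    interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <-
      m[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
      m[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
      m[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
      m[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
      m[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
      m[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
  }
  idx <- which(m & !interior, arr.ind = TRUE)
  sweep(idx, 2L, spacing, `*`)
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (n > 4000L) {  # deterministic thinning for very large surfaces
    pts <- pts[seq(1L, n, length.out = 4000L), , drop = FALSE]
    n <- nrow(pts)
  }
  best <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (pts[(i + 1L):n, 1L] - pts[i, 1L])^2 +
      (pts[(i + 1L):n, 2L] - pts[i, 2L])^2 +
      (if (ncol(pts) == 3L) (pts[(i + 1L):n, 3L] - pts[i, 3L])^2 else 0)
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Surface area of the 0.5-level set of a binary mask by marching tetrahedra.
# The indicator is first smoothed with a 3x3x3 box filter and mesh vertices
# are linearly interpolated at the 0.5 level: meshing the raw binary field
# keeps staircase jaggedness at the half-voxel scale (face counting
# overestimates a sphere by 3/2, binary midpoint meshes by ~25%), while the
# smoothed level set converges to the true surface with resolution.
mesh_surface_area <- function(m, spacing) {
  d <- dim(m)
  pad <- 2L
  p0 <- array(0, d + 2L * pad)
  p0[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- m
  # 3x3x3 box smoothing via shifted sums
  p <- array(0, dim(p0))
  dp <- dim(p0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    p[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <-
      p[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] +
      p0[2:(dp[1] - 1) + dx, 2:(dp[2] - 1) + dy, 2:(dp[3] - 1) + dz]
  }
  p <- p / 27
  # cell corner values: 8 shifted copies, bit order (dx, dy, dz)
  cd <- dp - 1L
  corner <- function(dx, dy, dz) {
    p[(1:cd[1]) + dx, (1:cd[2]) + dy, (1:cd[3]) + dz]
  }
  v <- vector("list", 8L)
  ofs <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  for (b in 1:8) v[[b]] <- corner(ofs[b, 1], ofs[b, 2], ofs[b, 3])
  inside8 <- lapply(v, function(z) z > 0.5)
  total <- inside8[[1L]]
  for (b in 2:8) total <- total + inside8[[b]]
  mixed <- which(total > 0L & total < 8L)
  if (!length(mixed)) return(0)
  vals <- vapply(1:8, function(b) as.numeric(v[[b]][mixed]),
                 numeric(length(mixed)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  cells <- arrayInd(mixed, cd)
  # 6-tetrahedra decomposition of the cube around the 0-7 diagonal
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  corner_xyz <- ofs  # voxel-unit offsets of the 8 corners
  area <- 0
  for (t in seq_len(nrow(tets))) {
    cv <- vals[, tets[t, ], drop = FALSE]
    bv <- cv > 0.5
    s <- rowSums(bv)
    act <- which(s > 0 & s < 4)
    if (!length(act)) next
    pc <- corner_xyz[tets[t, ], , drop = FALSE]  # 4 x 3 voxel coords
    for (i in act) {
      inside <- which(bv[i, ])
      outside <- which(!bv[i, ])
      base <- cells[i, ]
      # vertex where the 0.5 level crosses edge (a, b), linearly interpolated
      vert <- function(a, b) {
        tt <- (0.5 - cv[i, a]) / (cv[i, b] - cv[i, a])
        pc[a, ] + tt * (pc[b, ] - pc[a, ]) + base
      }
      if (length(inside) == 1L || length(inside) == 3L) {
        odd <- if (length(inside) == 1L) inside else outside
        rest <- setdiff(1:4, odd)
        p1 <- vert(odd, rest[1]); p2 <- vert(odd, rest[2]); p3 <- vert(odd, rest[3])
        area <- area + tri_area(p1, p2, p3, spacing)
      } else {
        a <- inside[1]; b <- inside[2]; cth <- outside[1]; dth <- outside[2]
        q1 <- vert(a, cth); q2 <- vert(a, dth); q3 <- vert(b, dth); q4 <- vert(b, cth)
        area <- area + tri_area(q1, q2, q3, spacing) +
          tri_area(q1, q3, q4, spacing)
      }
    }
  }
  area
}

tri_area <- function(p1, p2, p3, spacing) {
  u <- (p2 - p1) * spacing
  w <- (p3 - p1) * spacing
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  0.5 * sqrt(sum(cr^2))
}

## ---- first order ------------------------------------------------------

firstorder_features <- function(x, lv, voxel_volume) {
  n <- length(x)
  p <- tabulate(lv) / n
  p <- p[p > 0]
  qs <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  sub <- x[x >= qs[1] & x <= qs[4]]
  mu <- mean(x)
  vr <- mean((x - mu)^2)
  list(energy = sum(x^2), total_energy = sum(x^2) * voxel_volume,
       entropy = -sum(p * log2(p)),
       minimum = min(x), p10 = qs[1], p90 = qs[4], maximum = max(x),
       mean = mu, median = median(x), iqr = qs[3] - qs[2],
       range = max(x) - min(x), mad = mean(abs(x - mu)),
       rmad = if (length(sub)) mean(abs(sub - mean(sub))) else 0,
       rms = sqrt(mean(x^2)),
       skewness = if (vr > 0) mean((x - mu)^3) / vr^1.5 else 0,
       kurtosis = if (vr > 0) mean((x - mu)^4) / vr^2 else 0,
       variance = vr, uniformity = sum(p^2))
}

## ---- GLCM -------------------------------------------------------------

# Accumulate symmetric co-occurrence counts across slices for one in-plane
# offset (dr, dc); returns an ng x ng count matrix.
glcm_counts <- function(lv_arr, ng, dr, dc) {
  d <- dim(lv_arr)
  counts <- matrix(0, ng, ng)
  r1 <- seq_len(d[2] - abs(dr)); c1 <- seq_len(d[3] - abs(dc))
  if (dr < 0) r1 <- r1 - dr
  if (dc < 0) c1 <- c1 - dc
  for (s in seq_len(d[1])) {
    sl <- lv_arr[s, , ]
    if (all(is.na(sl))) next
    a <- sl[r1, c1, drop = FALSE]
    b <- sl[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts + t(counts)  # symmetric
}

glcm_from_offset <- function(lv_arr, ng, dr, dc) {
  counts <- glcm_counts(lv_arr, ng, dr, dc)
  tot <- sum(counts)
  if (tot == 0) return(matrix(1, 1, 1))  # degenerate ROI: single-entry matrix
  counts / tot
}

glcm_feature_set <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  pos <- P > 0
  corr <- if (sd_x > 0) {
    sum(P * (i - mu_x) * (j - mu_x)) / sd_x^2
  } else 0
  list(contrast = sum(P * (i - j)^2),
       dissimilarity = sum(P * abs(i - j)),
       idm = sum(P / (1 + (i - j)^2)),
       id = sum(P / (1 + abs(i - j))),
       asm = sum(P^2),
       joint_entropy = -sum(P[pos] * log2(P[pos])),
       correlation = corr,
       cluster_shade = sum(P * (i + j - 2 * mu_x)^3),
       cluster_prominence = sum(P * (i + j - 2 * mu_x)^4))
}

glcm_offsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

glcm_features <- function(lv_arr, ng) {
  per <- lapply(glcm_offsets(), function(o) {
    glcm_feature_set(glcm_from_offset(lv_arr, ng, o[1L], o[2L]))
  })
  nm <- names(per[[1L]])
  setNames(lapply(nm, function(k) {
    mean(vapply(per, function(f) f[[k]], numeric(1L)))
  }), nm)
}

## ---- GLRLM ------------------------------------------------------------

# Lines of a slice along an in-plane direction, in traversal order.
slice_lines <- function(sl, dir) {
  switch(dir,
         h = split(sl, row(sl)),
         v = split(sl, col(sl)),
         d = split(sl, row(sl) - col(sl)),
         a = split(sl, row(sl) + col(sl)))
}

glrlm_counts <- function(lv_arr, ng, dir) {
  d <- dim(lv_arr)
  max_run <- max(d[2L], d[3L])
  P <- matrix(0, ng, max_run)
  for (s in seq_len(d[1L])) {
    sl <- lv_arr[s, , ]
    if (all(is.na(sl))) next
    for (line in slice_lines(sl, dir)) {
      r <- rle(as.integer(line))
      keep <- !is.na(r$values)
      if (!any(keep)) next
      g <- r$values[keep]; len <- r$lengths[keep]
      for (k in seq_along(g)) P[g[k], len[k]] <- P[g[k], len[k]] + 1
    }
  }
  P
}

glrlm_feature_set <- function(P, np) {
  nr <- sum(P)
  if (nr == 0) return(list(sre = 0, lre = 0, gln = 0, rln = 0,
                           run_percentage = 0, grey_level_variance = 0))
  rl <- seq_len(ncol(P))
  gl <- seq_len(nrow(P))
  pr <- colSums(P)
  pg <- rowSums(P)
  pnorm_ <- P / nr
  mu_g <- sum(gl * rowSums(pnorm_))
  list(sre = sum(pr / rl^2) / nr,
       lre = sum(pr * rl^2) / nr,
       gln = sum(pg^2) / nr,
       rln = sum(pr^2) / nr,
       run_percentage = nr / np,
       grey_level_variance = sum(rowSums(pnorm_) * (gl - mu_g)^2))
}

glrlm_features <- function(lv_arr, ng) {
  np <- sum(!is.na(lv_arr))
  per <- lapply(c("h", "v", "d", "a"), function(dir) {
    glrlm_feature_set(glrlm_counts(lv_arr, ng, dir), np)
  })
  nm <- names(per[[1L]])
  setNames(lapply(nm, function(k) {
    mean(vapply(per, function(f) f[[k]], numeric(1L)))
  }), nm)
}

## ---- GLSZM ------------------------------------------------------------

# Connected zones (8-connectivity, per slice) of equal grey level.
glszm_counts <- function(lv_arr, ng) {
  d <- dim(lv_arr)
  zones <- list()
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  for (s in seq_len(d[1L])) {
    sl <- lv_arr[s, , ]
    if (all(is.na(sl))) next
    seen <- is.na(sl)
    for (start in which(!seen)) {
      if (seen[start]) next
      g <- sl[start]
      stack <- start
      seen[start] <- TRUE
      sz <- 0L
      while (length(stack)) {
        cur <- stack[length(stack)]
        stack <- stack[-length(stack)]
        sz <- sz + 1L
        cr <- (cur - 1L) %% d[2L] + 1L
        cc <- (cur - 1L) %/% d[2L] + 1L
        for (k in seq_len(nrow(nb))) {
          rr <- cr + nb[k, 1L]; cc2 <- cc + nb[k, 2L]
          if (rr < 1L || rr > d[2L] || cc2 < 1L || cc2 > d[3L]) next
          pos <- (cc2 - 1L) * d[2L] + rr
          if (!seen[pos] && !is.na(sl[pos]) && sl[pos] == g) {
            seen[pos] <- TRUE
            stack <- c(stack, pos)
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(g, sz)
    }
  }
  zn <- do.call(rbind, zones)
  max_sz <- max(zn[, 2L])
  P <- matrix(0, ng, max_sz)
  for (k in seq_len(nrow(zn))) {
    P[zn[k, 1L], zn[k, 2L]] <- P[zn[k, 1L], zn[k, 2L]] + 1
  }
  P
}

glszm_features <- function(lv_arr, ng) {
  np <- sum(!is.na(lv_arr))
  P <- glszm_counts(lv_arr, ng)
  nz <- sum(P)
  sz <- seq_len(ncol(P))
  ps <- colSums(P)
  pg <- rowSums(P)
  pn <- P / nz
  pos <- pn > 0
  list(sae = sum(ps / sz^2) / nz,
       lae = sum(ps * sz^2) / nz,
       gln = sum(pg^2) / nz,
       zsn = sum(ps^2) / nz,
       zone_percentage = nz / np,
       zone_entropy = -sum(pn[pos] * log2(pn[pos])))
}

## ---- GLDM -------------------------------------------------------------

# Dependence = 1 + number of in-plane in-mask neighbours with the same
# grey level (alpha = 0).
gldm_features <- function(lv_arr, ng) {
  d <- dim(lv_arr)
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  dep_list <- list()
  for (s in seq_len(d[1L])) {
    sl <- lv_arr[s, , ]
    inm <- which(!is.na(sl), arr.ind = TRUE)
    if (!nrow(inm)) next
    dep <- rep(1L, nrow(inm))
    for (k in seq_len(nrow(nb))) {
      rr <- inm[, 1L] + nb[k, 1L]; cc <- inm[, 2L] + nb[k, 2L]
      ok <- rr >= 1L & rr <= d[2L] & cc >= 1L & cc <= d[3L]
      same <- ok
      same[ok] <- !is.na(sl[cbind(rr[ok], cc[ok])]) &
        sl[cbind(rr[ok], cc[ok])] == sl[inm[ok, , drop = FALSE]]
      dep <- dep + as.integer(same)
    }
    dep_list[[length(dep_list) + 1L]] <- cbind(sl[inm], dep)
  }
  gd <- do.call(rbind, dep_list)
  nd <- max(gd[, 2L])
  P <- matrix(0, ng, nd)
  for (k in seq_len(nrow(gd))) {
    P[gd[k, 1L], gd[k, 2L]] <- P[gd[k, 1L], gd[k, 2L]] + 1
  }
  nz <- sum(P)
  dd <- seq_len(ncol(P))
  pd <- colSums(P)
  pg <- rowSums(P)
  pn <- P / nz
  pos <- pn > 0
  list(sde = sum(pd / dd^2) / nz,
       lde = sum(pd * dd^2) / nz,
       gln = sum(pg^2) / nz,
       dn = sum(pd^2) / nz,
       dependence_entropy = -sum(pn[pos] * log2(pn[pos])))
}

## ---- NGTDM ------------------------------------------------------------

ngtdm_features <- function(lv_arr, ng) {
  d <- dim(lv_arr)
  nb <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  s_i <- numeric(ng)
  n_i <- numeric(ng)
  for (s in seq_len(d[1L])) {
    sl <- lv_arr[s, , ]
    inm <- which(!is.na(sl), arr.ind = TRUE)
    if (!nrow(inm)) next
    nsum <- numeric(nrow(inm))
    ncnt <- numeric(nrow(inm))
    for (k in seq_len(nrow(nb))) {
      rr <- inm[, 1L] + nb[k, 1L]; cc <- inm[, 2L] + nb[k, 2L]
      ok <- rr >= 1L & rr <= d[2L] & cc <= d[3L] & cc >= 1L
      val <- rep(NA_integer_, nrow(inm))
      val[ok] <- sl[cbind(rr[ok], cc[ok])]
      has <- !is.na(val)
      nsum[has] <- nsum[has] + val[has]
      ncnt[has] <- ncnt[has] + 1
    }
    g <- sl[inm]
    has_nb <- ncnt > 0
    diffs <- abs(g[has_nb] - nsum[has_nb] / ncnt[has_nb])
    for (lvl in unique(g[has_nb])) {
      sel <- g[has_nb] == lvl
      s_i[lvl] <- s_i[lvl] + sum(diffs[sel])
      n_i[lvl] <- n_i[lvl] + sum(sel)
    }
  }
  nvp <- sum(n_i)
  if (nvp == 0) {
    # no voxel has an in-plane neighbour (e.g. a single-voxel ROI)
    return(list(coarseness = 1e6, contrast = 0, busyness = 0,
                complexity = 0, strength = 0))
  }
  p_i <- n_i / nvp
  present <- which(p_i > 0)
  ngp <- length(present)
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- 0
  busyness <- 0
  complexity <- 0
  strength <- 0
  if (ngp > 1) {
    pr <- expand.grid(i = present, j = present)
    pi_ <- p_i[pr$i]; pj <- p_i[pr$j]
    contrast <- sum(pi_ * pj * (pr$i - pr$j)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / nvp
    bd <- sum(abs(pr$i * pi_ - pr$j * pj)) / 2  # each unordered pair once
    busyness <- if (bd > 0) sum(p_i * s_i) / (2 * bd) else 0
    complexity <- sum(abs(pr$i - pr$j) *
                      (pi_ * s_i[pr$i] + pj * s_i[pr$j]) / (pi_ + pj)) / nvp
    sden <- sum(s_i)
    strength <- if (sden > 0) {
      sum((pi_ + pj) * (pr$i - pr$j)^2) / sden
    } else 0
  }
  list(coarseness = coarseness, contrast = contrast, busyness = busyness,
       complexity = complexity, strength = strength)
}
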