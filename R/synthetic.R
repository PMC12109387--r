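# Synthetic labelled dental arches. Teeth are superquadric crowns
# (|x/a|^p + |y/b|^p + |z/c|^p = 1, exponent varying from blade-like incisors
# to rounded-square molars) planted along a parabolic arch curve; the gingiva
# is the upper half of a tube swept along the same curve. Scenario modifiers
# emulate the clinically common situations: crowding, a missing tooth, a
# malformed tooth and a partially erupted last molar.

# per-position crown half-axes (mm): mesiodistal a, buccolingual b, height c,
# and superquadric exponent p (p = 2 ellipsoid, larger = boxier)
tooth_shape_table <- function() {
  data.frame(
    pos = 1:8,
    a = c(4.3, 3.4, 3.9, 3.6, 3.6, 5.3, 5.1, 4.6),
    b = c(3.5, 3.3, 4.0, 4.7, 4.9, 5.6, 5.4, 5.0),
    c = c(5.5, 5.0, 5.5, 4.5, 4.2, 4.0, 3.8, 3.5),
    p = c(3.0, 3.0, 2.2, 2.6, 2.6, 3.4, 3.4, 3.0)
  )
}

#' Specify a synthetic dental arch
#'
#' @param scenario one of `"normal"`, `"crowded"`, `"missing"`,
#'   `"malformed"`, `"partial_eruption"` (the five clinically motivated
#'   situations the generator emulates).
#' @param jaw `"upper"` (crowns point -z), `"lower"` (crowns +z) or
#'   `"both"` (two opposed arches in one cloud, as in a full-mouth record).
#' @param teeth_per_quadrant up to 8.
#' @param points_per_cloud total points sampled (default 8192).
#' @param noise_sd isotropic Gaussian coordinate noise, mm (default 0.1,
#'   the order of intraoral-scanner surface noise).
#' @param arch_half_width,arch_depth parabolic midline curve parameters, mm.
#' @param gingiva_radius radius of the gingival ridge tube, mm.
#' @param seed RNG seed; generation is fully deterministic for a fixed
#'   `arch_spec`.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(scenario = c("normal", "crowded", "missing",
                                   "malformed", "partial_eruption"),
                      jaw = c("upper", "lower", "both"),
                      teeth_per_quadrant = 8L,
                      points_per_cloud = 8192L,
                      noise_sd = 0.1,
                      arch_half_width = 27, arch_depth = 30,
                      gingiva_radius = 6, seed = 1L) {
  scenario <- match.arg(scenario)
  jaw <- match.arg(jaw)
  stopifnot(teeth_per_quadrant >= 1L, teeth_per_quadrant <= 8L,
            points_per_cloud >= 100L, noise_sd >= 0)
  structure(list(scenario = scenario, jaw = jaw,
                 teeth_per_quadrant = as.integer(teeth_per_quadrant),
                 points_per_cloud = as.integer(points_per_cloud),
                 noise_sd = noise_sd, arch_half_width = arch_half_width,
                 arch_depth = arch_depth, gingiva_radius = gingiva_radius,
                 seed = as.integer(seed)),
            class = "arch_spec")
}

# arch midline curve and arc-length parametrisation
arch_curve <- function(W, D, n = 400L) {
  t <- seq(-1, 1, length.out = n)
  x <- W * t
  y <- D * (1 - t^2)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(t = t, x = x, y = y, s = s / s[length(s)])
}

curve_at <- function(curve, frac, W, D) {
  t <- stats::approx(curve$s, curve$t, xout = frac, rule = 2)$y
  list(t = t, x = W * t, y = D * (1 - t^2),
       angle = atan2(-2 * D * t, W))   # tangent direction in the xy plane
}

# exact surface sample of a superquadric |x/a|^p + |y/b|^p + |z/c|^p = 1
sample_superquadric <- function(n, axes, p) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (abs(u[, 1] / axes[1])^p + abs(u[, 2] / axes[2])^p +
          abs(u[, 3] / axes[3])^p)^(-1 / p)
  u * r
}

superquadric_value <- function(pts_local, axes, p) {
  (abs(pts_local[, 1] / axes[1])^p + abs(pts_local[, 2] / axes[2])^p +
     abs(pts_local[, 3] / axes[3])^p)^(1 / p)
}

rot_z <- function(phi) {
  matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# build the tooth layout of one arch half-pair (one jaw); returns a list of
# per-tooth descriptors in the jaw's canonical frame (crowns +z, crest z = 0)
layout_teeth <- function(spec, quad_pair) {
  q <- spec$teeth_per_quadrant
  shapes <- tooth_shape_table()
  n_teeth <- 2L * q
  # left-to-right positions: q..1 in the first quadrant, 1..q in the second
  pos_seq <- c(rev(seq_len(q)), seq_len(q))
  quad_seq <- rep(quad_pair, each = q)
  fr <- (seq_len(n_teeth) - 0.5) / n_teeth
  if (spec$scenario == "crowded") {
    # spacing shrunk 30-50%, concentrated anteriorly (incisor crowding);
    # molars near the arch ends barely move
    shrink <- stats::runif(1, 0.5, 0.7)
    dev <- fr - 0.5
    w <- shrink + (1 - shrink) * pmin(1, (2 * abs(dev))^1.5)
    fr <- 0.5 + dev * w
  }
  fr <- fr + stats::runif(n_teeth, -0.1, 0.1) / n_teeth
  teeth <- vector("list", n_teeth)
  for (i in seq_len(n_teeth)) {
    pos <- pos_seq[i]
    sh <- shapes[shapes$pos == pos, ]
    axes <- c(sh$a, sh$b, sh$c) * stats::runif(3, 0.92, 1.08)
    teeth[[i]] <- list(
      class = (quad_seq[i] - 1L) * 8L + pos,
      pos = pos, frac = fr[i], axes = axes, p = sh$p,
      a_ref = axes[1],                       # placement-feasibility width
      rot_jitter = stats::runif(1, -5, 5) * pi / 180,
      eruption = 1)
  }
  teeth
}

# generate one jaw in its canonical frame; returns points, labels, meta
generate_jaw <- function(spec, quad_pair) {
  W <- spec$arch_half_width * if (quad_pair[1] >= 3L) 0.94 else 1
  D <- spec$arch_depth * if (quad_pair[1] >= 3L) 0.97 else 1
  R <- spec$gingiva_radius
  curve <- arch_curve(W, D)

  for (try in 1:10) {
    teeth <- layout_teeth(spec, quad_pair)
    # scenario modifiers
    if (spec$scenario == "missing" && length(teeth) > 1L) {
      drop_i <- sample.int(length(teeth), 1L)
      teeth <- teeth[-drop_i]
    }
    if (spec$scenario == "malformed") {
      mi <- sample.int(length(teeth), 1L)
      teeth[[mi]]$axes <- teeth[[mi]]$axes * stats::runif(3, 0.4, 1.6)
    }
    if (spec$scenario == "partial_eruption") {
      # last molar of a random side
      pos_max <- max(vapply(teeth, `[[`, 0L, "pos"))
      cand <- which(vapply(teeth, `[[`, 0L, "pos") == pos_max)
      ei <- cand[sample.int(length(cand), 1L)]
      teeth[[ei]]$eruption <- stats::runif(1, 0.2, 0.6)
    }
    # place on the curve
    for (i in seq_along(teeth)) {
      at <- curve_at(curve, teeth[[i]]$frac, W, D)
      teeth[[i]]$center <- c(at$x, at$y, 0.25 * teeth[[i]]$axes[3])
      teeth[[i]]$angle <- at$angle + teeth[[i]]$rot_jitter
    }
    # overlap check on adjacent crowns (near-contact allowed when crowded;
    # a malformed crown may legitimately contact its neighbours, so the
    # check uses the pre-malformation reference widths)
    lim <- if (spec$scenario == "crowded") 0.25 else 0.40
    ok <- TRUE
    if (length(teeth) > 1L) {
      for (i in seq_len(length(teeth) - 1L)) {
        d <- sqrt(sum((teeth[[i]]$center[1:2] - teeth[[i + 1]]$center[1:2])^2))
        if (d < lim * (teeth[[i]]$a_ref + teeth[[i + 1]]$a_ref)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) break
    if (try == 10L) stop("geometry error: could not place teeth without overlap")
  }

  # point budget: proportional to rough surface areas
  areas <- vapply(teeth, function(th) {
    4 * (th$axes[1] * th$axes[2] + th$axes[2] * th$axes[3] +
           th$axes[1] * th$axes[3]) * 0.65 * th$eruption
  }, numeric(1))
  gum_area <- pi * R * sum(sqrt(diff(curve$x)^2 + diff(curve$y)^2))
  wts <- c(areas, gum_area)
  n_target <- spec$points_per_cloud
  alloc <- pmax(8L, round(n_target * wts / sum(wts)))

  pts_all <- NULL
  lab_all <- integer()
  over <- 1.8
  for (rep_i in 1:5) {
    pts_list <- vector("list", length(teeth) + 1L)
    lab_list <- vector("list", length(teeth) + 1L)
    for (i in seq_along(teeth)) {
      th <- teeth[[i]]
      n_i <- ceiling(alloc[i] * over)
      loc <- sample_superquadric(n_i, th$axes, th$p)
      pw <- loc %*% t(rot_z(th$angle))
      pw <- sweep(pw, 2, th$center, `+`)
      # visibility: cull points buried in the gingival ridge
      keep <- !inside_gum_tube(pw, curve, W, D, R)
      # partial eruption: clip below the eruption plane
      z_top <- th$center[3] + th$axes[3]
      z_cut <- z_top - th$eruption * z_top
      teeth[[i]]$z_cut <- z_cut
      if (th$eruption < 1) keep <- keep & pw[, 3] >= z_cut
      pts_list[[i]] <- pw[keep, , drop = FALSE]
      lab_list[[i]] <- rep.int(th$class, sum(keep))
    }
    # gingiva: upper half-tube along the curve
    n_g <- ceiling(alloc[length(alloc)] * over)
    fr <- stats::runif(n_g)
    at <- curve_at(curve, fr, W, D)
    phi <- stats::runif(n_g, -pi / 2, pi / 2)
    nx <- -sin(at$angle)                       # horizontal normal of the curve
    ny <- cos(at$angle)
    gx <- at$x + nx * R * sin(phi)
    gy <- at$y + ny * R * sin(phi)
    gz <- -R + R * cos(phi)
    gpts <- cbind(gx, gy, gz)
    gkeep <- !inside_any_tooth(gpts, teeth)
    pts_list[[length(teeth) + 1L]] <- gpts[gkeep, , drop = FALSE]
    lab_list[[length(teeth) + 1L]] <- rep.int(0L, sum(gkeep))

    pts_all <- do.call(rbind, pts_list)
    lab_all <- unlist(lab_list)
    if (nrow(pts_all) >= n_target) break
    over <- over * 1.6
  }
  keep <- sample.int(nrow(pts_all), n_target)
  list(points = pts_all[keep, , drop = FALSE], labels = lab_all[keep],
       teeth = teeth)
}

inside_gum_tube <- function(pts, curve, W, D, R, margin = 0.05) {
  # nearest axis sample of the tube (axis at z = -R along the curve)
  ax <- cbind(curve$x, curve$y, -R)
  d2min <- rep(Inf, nrow(pts))
  step <- 4L
  idx <- seq(1L, nrow(ax), by = step)
  for (i in idx) {
    d2 <- (pts[, 1] - ax[i, 1])^2 + (pts[, 2] - ax[i, 2])^2 +
      (pts[, 3] - ax[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  sqrt(d2min) < R - margin
}

inside_any_tooth <- function(pts, teeth, tol = 1e-3) {
  inside <- rep(FALSE, nrow(pts))
  for (th in teeth) {
    reach <- max(th$axes) + 0.5
    near <- which(abs(pts[, 1] - th$center[1]) < reach &
                    abs(pts[, 2] - th$center[2]) < reach &
                    !inside)
    if (!length(near)) next
    # world = local %*% t(Rz(angle)), so local = world %*% Rz(angle)
    loc <- sweep(pts[near, , drop = FALSE], 2, th$center) %*% rot_z(th$angle)
    # account for eruption clipping: a culled region cannot shadow gum points
    f <- superquadric_value(loc, th$axes, th$p)
    inside[near[f < 1 - tol]] <- TRUE
  }
  inside
}

#' Generate a labelled synthetic dental arch
#'
#' Surface-samples each tooth crown (label = its FDI class index) and the
#' gingival ridge (label 0) according to the scenario in `spec`, applies
#' isotropic Gaussian noise of `spec$noise_sd`, and returns exactly
#' `spec$points_per_cloud` points. Deterministic for a fixed `spec$seed`.
#' Upper-jaw crowns point in -z and lower-jaw crowns in +z, so the two jaws
#' remain distinguishable after normalization.
#'
#' @param spec an [arch_spec()].
#' @return A [labeled_cloud()] (scanner units, un-normalized) with attribute
#'   `"arch_meta"`: list with `scenario`, `jaw`, and `teeth`, the per-tooth
#'   descriptors (class, world-frame center, half-axes, exponent `p`,
#'   rotation `angle` about z, eruption fraction) used by the geometry;
#'   tooth surface points satisfy
#'   `superquadric_value(Rz(-angle) (x - center), axes, p) = 1` up to noise.
#' @export
generate_arch <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  flip_z <- function(jw) {
    jw$points[, 3] <- -jw$points[, 3]
    for (i in seq_along(jw$teeth)) {
      jw$teeth[[i]]$center[3] <- -jw$teeth[[i]]$center[3]
      if (!is.null(jw$teeth[[i]]$z_cut)) {
        jw$teeth[[i]]$z_cut <- -jw$teeth[[i]]$z_cut
      }
      jw$teeth[[i]]$flipped <- TRUE
    }
    jw
  }
  shift_z <- function(jw, dz) {
    jw$points[, 3] <- jw$points[, 3] + dz
    for (i in seq_along(jw$teeth)) {
      jw$teeth[[i]]$center[3] <- jw$teeth[[i]]$center[3] + dz
      if (!is.null(jw$teeth[[i]]$z_cut)) {
        jw$teeth[[i]]$z_cut <- jw$teeth[[i]]$z_cut + dz
      }
    }
    jw
  }

  if (spec$jaw == "upper") {
    jw <- flip_z(generate_jaw(spec, c(1L, 2L)))
    parts <- list(jw)
  } else if (spec$jaw == "lower") {
    parts <- list(generate_jaw(spec, c(4L, 3L)))
  } else {
    # a scenario complication affects one jaw; the other stays normal
    affected <- sample(c("upper", "lower"), 1L)
    spec_up <- spec
    spec_lo <- spec
    if (spec$scenario != "normal") {
      if (affected == "upper") spec_lo$scenario <- "normal"
      else spec_up$scenario <- "normal"
    }
    spec_up$points_per_cloud <- spec$points_per_cloud %/% 2L
    spec_lo$points_per_cloud <- spec$points_per_cloud - spec_up$points_per_cloud
    up <- shift_z(flip_z(generate_jaw(spec_up, c(1L, 2L))), 14)
    lo <- generate_jaw(spec_lo, c(4L, 3L))
    parts <- list(up, lo)
  }
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  lab <- unlist(lapply(parts, `[[`, "labels"))
  if (spec$noise_sd > 0) {
    pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$noise_sd),
                        nrow(pts), 3L)
  }
  cl <- labeled_cloud(pts, labels = lab, n_classes = 33L)
  attr(cl, "arch_meta") <- list(
    scenario = spec$scenario, jaw = spec$jaw,
    teeth = do.call(c, lapply(parts, `[[`, "teeth")), seed = spec$seed)
  cl
}

#' Generate a dataset of synthetic arches
#'
#' Draws a scenario per cloud from `scenario_mix` and a jaw (upper/lower,
#' 50/50) per cloud, generates each arch with its own derived seed and
#' returns the clouds plus a manifest. Deterministic for a fixed `seed`.
#'
#' @param n_clouds number of clouds.
#' @param scenario_mix named nonnegative proportions over the five scenarios,
#'   summing to 1. The default mix leans towards normal dentition with the
#'   four complications represented.
#' @param seed dataset seed.
#' @param points_per_cloud,noise_sd,teeth_per_quadrant forwarded to
#'   [arch_spec()].
#' @param jaw fix the jaw for every cloud instead of drawing it.
#' @return list with `clouds` (list of [labeled_cloud()]) and `manifest`
#'   (data.frame: cloud_id, scenario, jaw, seed, spec_hash, n_points,
#'   classes present).
#' @export
generate_dataset <- function(n_clouds,
                             scenario_mix = c(normal = 0.4, crowded = 0.2,
                                              missing = 0.15, malformed = 0.1,
                                              partial_eruption = 0.15),
                             seed = 1L, points_per_cloud = 8192L,
                             noise_sd = 0.1, teeth_per_quadrant = 8L,
                             jaw = NULL) {
  if (abs(sum(scenario_mix) - 1) > 1e-8 || any(scenario_mix < 0)) {
    stop("scenario_mix proportions must be nonnegative and sum to 1")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  scen <- sample(names(scenario_mix), n_clouds, replace = TRUE,
                 prob = scenario_mix)
  jaws <- if (is.null(jaw)) {
    sample(c("upper", "lower"), n_clouds, replace = TRUE)
  } else rep(jaw, n_clouds)
  seeds <- sample.int(2^30, n_clouds)
  clouds <- vector("list", n_clouds)
  rows <- vector("list", n_clouds)
  for (i in seq_len(n_clouds)) {
    sp <- arch_spec(scenario = scen[i], jaw = jaws[i],
                    teeth_per_quadrant = teeth_per_quadrant,
                    points_per_cloud = points_per_cloud,
                    noise_sd = noise_sd, seed = seeds[i])
    clouds[[i]] <- generate_arch(sp)
    present <- sort(unique(clouds[[i]]$labels))
    rows[[i]] <- data.frame(
      cloud_id = sprintf("arch_%04d", i), scenario = scen[i], jaw = jaws[i],
      seed = seeds[i], spec_hash = spec_hash(sp),
      n_points = nrow(clouds[[i]]$points),
      n_classes_present = length(present),
      classes = paste(present, collapse = ";"))
  }
  list(clouds = clouds, manifest = do.call(rbind, rows))
}

# small rolling-hash fingerprint of a spec (manifest bookkeeping)
spec_hash <- function(spec) {
  s <- paste(names(unlist(spec)), unlist(spec), collapse = "|")
  b <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(b)) h <- (h * 131 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}
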