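#' Canonical posture archetypes
#'
#' A library of five named 19-joint skeleton poses (57-dim feature vectors,
#' coordinates in metres: x forward, y lateral, z up): `upright_walk`,
#' `lean_pick` (trunk pitched far forward, hands reaching toward the floor),
#' `lean_place` (moderate lean, hands forward at table height),
#' `extended_hands_walk` (upright trunk, arms horizontal), and `squat`.
#' Upright and leaning poses differ chiefly in the trunk joints; the
#' extended-hands pose differs from plain walking chiefly in the arm joints.
#' That geometry is what lets cosine-driven groupings (dominated by trunk
#' inclination) and Euclidean-driven groupings (trunk and hand positions)
#' diverge qualitatively.
#'
#' @return A list of class `archetype_library`: named numeric vectors of
#'   length 57, with a `joint_names` attribute (19 labels).
#' @export
default_archetypes <- function() {
  joints <- c("pelvis", "spine", "chest", "neck", "head",
              "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
              "l_wrist", "r_wrist", "l_hip", "r_hip",
              "l_knee", "r_knee", "l_ankle", "r_ankle", "l_foot", "r_foot")
  pose <- function(trunk, l_arm, r_arm, legs) {
    # trunk: 5 x 3; arms: 3 x 3 each (shoulder, elbow, wrist); legs: 8 x 3
    p <- rbind(trunk,
               l_arm[1, ], r_arm[1, ], l_arm[2, ], r_arm[2, ],
               l_arm[3, ], r_arm[3, ],
               legs)
    as.numeric(t(p))
  }
  mirror <- function(a) { a[, 2] <- -a[, 2]; a }
  legs_stand <- rbind(
    c(0, 0.10, 0.95), c(0, -0.10, 0.95),  # hips
    c(0, 0.10, 0.50), c(0, -0.10, 0.50),  # knees
    c(0, 0.10, 0.10), c(0, -0.10, 0.10),  # ankles
    c(0.12, 0.10, 0.02), c(0.12, -0.10, 0.02)) # feet
  trunk_up <- rbind(c(0, 0, 1.00), c(0, 0, 1.20), c(0, 0, 1.40),
                    c(0, 0, 1.55), c(0, 0, 1.70))
  arm_down <- rbind(c(0, 0.20, 1.50), c(0, 0.25, 1.20), c(0, 0.27, 0.95))
  arm_fwd <- rbind(c(0, 0.20, 1.50), c(0.25, 0.22, 1.50), c(0.50, 0.24, 1.50))

  lib <- list(
    upright_walk = pose(trunk_up, arm_down, mirror(arm_down), legs_stand),
    lean_pick = pose(
      rbind(c(0, 0, 0.95), c(0.15, 0, 1.08), c(0.30, 0, 1.15),
            c(0.42, 0, 1.18), c(0.52, 0, 1.20)),
      rbind(c(0.40, 0.20, 1.15), c(0.50, 0.22, 0.85), c(0.55, 0.24, 0.50)),
      mirror(rbind(c(0.40, 0.20, 1.15), c(0.50, 0.22, 0.85),
                   c(0.55, 0.24, 0.50))),
      legs_stand),
    lean_place = pose(
      rbind(c(0, 0, 1.00), c(0.08, 0, 1.18), c(0.16, 0, 1.33),
            c(0.22, 0, 1.45), c(0.28, 0, 1.55)),
      rbind(c(0.20, 0.20, 1.42), c(0.40, 0.22, 1.25), c(0.60, 0.24, 1.10)),
      mirror(rbind(c(0.20, 0.20, 1.42), c(0.40, 0.22, 1.25),
                   c(0.60, 0.24, 1.10))),
      legs_stand),
    extended_hands_walk = pose(trunk_up, arm_fwd, mirror(arm_fwd), legs_stand),
    squat = pose(
      rbind(c(0, 0, 0.55), c(0.08, 0, 0.75), c(0.15, 0, 0.95),
            c(0.20, 0, 1.10), c(0.25, 0, 1.22)),
      rbind(c(0.18, 0.20, 1.05), c(0.30, 0.22, 0.85), c(0.35, 0.24, 0.60)),
      mirror(rbind(c(0.18, 0.20, 1.05), c(0.30, 0.22, 0.85),
                   c(0.35, 0.24, 0.60))),
      rbind(c(0, 0.10, 0.50), c(0, -0.10, 0.50),
            c(0.30, 0.12, 0.45), c(0.30, -0.12, 0.45),
            c(0, 0.10, 0.10), c(0, -0.10, 0.10),
            c(0.12, 0.10, 0.02), c(0.12, -0.10, 0.02)))
  )
  structure(lib, joint_names = joints, class = "archetype_library")
}

#' Script describing a synthetic activity
#'
#' Defines the play order of posture archetypes, how long each is held, how
#' long the smooth transitions between them last, and the per-coordinate
#' noise and gait-oscillation parameters. Defaults emulate a pick-and-place
#' style activity recorded at 15 fps: sustained dwell periods, short linear
#' transitions, small Gaussian keypoint jitter, and a periodic sinusoidal
#' limb offset standing in for the gait cycle.
#'
#' @param archetypes Character vector of archetype names in play order.
#' @param dwell Frames each archetype is held (recycled per segment).
#' @param transition Frames of linear interpolation between consecutive
#'   archetypes (0 for hard cuts).
#' @param noise_sd Gaussian jitter sd per coordinate, metres (default 0.01,
#'   typical keypoint noise).
#' @param gait_amplitude Amplitude (metres) of the sinusoidal forward offset
#'   applied to wrists, knees, ankles and feet (default 0.03).
#' @param gait_period Gait period in seconds (default 1).
#' @param fps Frames per second (default 15).
#' @param seed RNG seed.
#' @return A list of class `activity_script`.
#' @export
activity_script <- function(archetypes = c("upright_walk", "lean_pick",
                                           "upright_walk", "lean_place"),
                            dwell = 100, transition = 10,
                            noise_sd = 0.01, gait_amplitude = 0.03,
                            gait_period = 1, fps = 15, seed = 1L) {
  if (length(archetypes) == 0) stop("empty script", call. = FALSE)
  dwell <- rep_len(as.integer(dwell), length(archetypes))
  if (any(dwell <= 0)) stop("dwell must be positive", call. = FALSE)
  if (transition < 0) stop("transition must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(archetypes = archetypes, dwell = dwell,
         transition = as.integer(transition), noise_sd = noise_sd,
         gait_amplitude = gait_amplitude, gait_period = gait_period,
         fps = fps, seed = as.integer(seed)),
    class = "activity_script"
  )
}

#' Generate a synthetic activity sequence with ground truth
#'
#' Builds a posture sequence from an [activity_script()]: each archetype is
#' held for its dwell period, consecutive archetypes are joined by linear
#' interpolation over the transition window, and every frame receives
#' i.i.d. Gaussian jitter plus a sinusoidal forward offset on the limb
#' joints (alternating left/right phase) emulating the gait cycle.
#' Ground-truth labels switch to the incoming archetype at the interpolation
#' midpoint; the first frame carrying each new label is recorded in the
#' `boundaries` attribute, the reference for transition-tolerance checks.
#'
#' @param script An [activity_script()].
#' @param library An [default_archetypes()]-style library containing every
#'   scripted archetype.
#' @return A [posture_sequence()] with `segment_labels`; total length
#'   `sum(dwell) + (n_segments - 1) * transition`. Attributes: `boundaries`
#'   (ground-truth segment-change frames) and `script`.
#' @export
make_activity_sequence <- function(script, library = default_archetypes()) {
  stopifnot(inherits(script, "activity_script"))
  missing <- setdiff(script$archetypes, names(library))
  if (length(missing) > 0) {
    stop("archetype(s) not in library: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(script$seed)
  nseg <- length(script$archetypes)
  tr <- script$transition
  d <- length(library[[script$archetypes[1]]])

  rows <- list()
  labels <- character(0)
  for (i in seq_len(nseg)) {
    a <- library[[script$archetypes[i]]]
    rows[[length(rows) + 1]] <- matrix(a, nrow = script$dwell[i], ncol = d,
                                       byrow = TRUE)
    labels <- c(labels, rep(script$archetypes[i], script$dwell[i]))
    if (i < nseg && tr > 0) {
      b <- library[[script$archetypes[i + 1]]]
      alpha <- seq_len(tr) / (tr + 1)
      rows[[length(rows) + 1]] <- outer(1 - alpha, a) + outer(alpha, b)
      n_out <- ceiling(tr / 2) # outgoing label up to the midpoint
      labels <- c(labels, rep(script$archetypes[i], n_out),
                  rep(script$archetypes[i + 1], tr - n_out))
    }
  }
  X <- do.call(rbind, rows)
  tt <- nrow(X)

  # gait: sinusoidal forward (x) offset on wrists, knees, ankles, feet,
  # alternating phase left/right
  period <- max(script$gait_period * script$fps, 2)
  phase <- sin(2 * pi * seq_len(tt) / period) * script$gait_amplitude
  limb_left <- c("l_wrist", "l_knee", "l_ankle", "l_foot")
  limb_right <- c("r_wrist", "r_knee", "r_ankle", "r_foot")
  joints <- attr(library, "joint_names")
  xcol <- function(nm) (match(nm, joints) - 1) * 3 + 1
  for (nm in limb_left) X[, xcol(nm)] <- X[, xcol(nm)] + phase
  for (nm in limb_right) X[, xcol(nm)] <- X[, xcol(nm)] - phase

  if (script$noise_sd > 0) {
    X <- X + matrix(rnorm(tt * d, sd = script$noise_sd), tt, d)
  }

  out <- posture_sequence(X, fps = script$fps,
                          joint_names = joints,
                          segment_labels = labels)
  change <- which(labels[-1] != labels[-tt]) + 1L
  attr(out, "boundaries") <- change
  attr(out, "script") <- script
  out
}

#' Generate well-separated Gaussian posture clusters
#'
#' Draws `k` isotropic Gaussian clusters in `d` dimensions with known
#' labels. Cluster centres sit on a sphere of radius `separation * sd`
#' about the origin (random directions, re-drawn until all mutual centre
#' distances are at least `separation * sd`), so the clusters are separated
#' both in Euclidean distance and in direction — the latter is what the
#' cosine metric sees, and real skeleton coordinates likewise sit far from
#' the camera origin. Errors out when the requested spacing cannot be
#' placed (e.g. many clusters in very few dimensions).
#'
#' @param k Number of clusters.
#' @param d Dimension (default 57).
#' @param separation Centre spacing in units of the within-cluster sd
#'   (default 10).
#' @param n_per_cluster Points per cluster (default 100).
#' @param sd Within-cluster standard deviation per coordinate (default 1).
#' @param seed RNG seed.
#' @return A list with `data` (`k * n_per_cluster` rows, cluster blocks in
#'   order), `labels` (integer, `1..k`), and `centers` (`k x d`).
#' @export
make_gaussian_postures <- function(k, d = 57, separation = 10,
                                   n_per_cluster = 100, sd = 1, seed = 1L) {
  stopifnot(k >= 1, d >= 1, n_per_cluster >= 1, sd > 0, separation > 0)
  set.seed(seed)
  r <- separation * sd
  centers <- matrix(NA_real_, k, d)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      u <- rnorm(d)
      cand <- r * u / sqrt(sum(u^2))
      if (i == 1 ||
          min(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                 2, cand)^2))) >= r) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("cannot place ", k, " centres at spacing ", r, " in ", d,
           " dimensions", call. = FALSE)
    }
  }
  data <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per_cluster * d, sd = sd), n_per_cluster, d) +
      matrix(centers[i, ], n_per_cluster, d, byrow = TRUE)
  }))
  list(data = data, labels = rep(seq_len(k), each = n_per_cluster),
       centers = centers)
}

#' Write the ground-truth labels of a synthetic sequence
#'
#' Companion output to [write_sequence()]: a CSV with one row per frame
#' (`frame`, `segment_id`, `archetype_name`), where `segment_id` increments
#' at every ground-truth boundary.
#'
#' @param seq A labelled [posture_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(seq, path) {
  stopifnot(inherits(seq, "posture_sequence"))
  lab <- seq$segment_labels
  if (is.null(lab)) stop("sequence has no segment labels", call. = FALSE)
  seg <- cumsum(c(1L, as.integer(lab[-1] != lab[-length(lab)])))
  df <- data.frame(frame = seq_along(lab), segment_id = seg,
                   archetype_name = lab)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
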