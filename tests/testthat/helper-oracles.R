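# Independent reference implementations used as oracles. These are written
# as naive double/triple loops against the definitions, deliberately
# avoiding the package's vectorized bookkeeping, so that agreement is a
# genuine cross-check and not a tautology.

dist3 <- function(p, q) sqrt(sum((p - q)^2))

point_of <- function(ps, label) {
  row <- ps$points[ps$points$label == label, ]
  as.numeric(row[1, c("x", "y", "z")])
}

optode_labels <- function(ps) {
  ps$points$label[!is_fiducial(ps$points$label)]
}

# flat distance collection of the between-subject variability analysis
oracle_cap_fixation <- function(sets, method = "pairwise") {
  labels <- unique(unlist(lapply(sets, optode_labels)))
  out <- numeric(0)
  for (l in labels) {
    have <- Filter(function(s) l %in% s$points$label, sets)
    if (length(have) < 2) next
    if (method == "pairwise") {
      for (i in seq_along(have)) {
        for (j in seq_along(have)) {
          if (i < j) {
            out <- c(out, dist3(point_of(have[[i]], l),
                                point_of(have[[j]], l)))
          }
        }
      }
    } else {
      ctr <- c(0, 0, 0)
      for (s in have) ctr <- ctr + point_of(s, l)
      ctr <- ctr / length(have)
      for (s in have) out <- c(out, dist3(point_of(s, l), ctr))
    }
  }
  out
}

oracle_accuracy <- function(scans, mri, mode) {
  out <- numeric(0)
  for (scan in scans) {
    aligned <- align(scan, mri, mode = mode)$probe_set
    for (l in optode_labels(mri)) {
      if (l %in% aligned$points$label) {
        out <- c(out, dist3(point_of(aligned, l), point_of(mri, l)))
      }
    }
  }
  out
}

oracle_reproducibility <- function(scans, mode) {
  out <- numeric(0)
  for (i in seq_along(scans)) {
    for (j in seq_along(scans)) {
      if (i < j) {
        aligned <- align(scans[[j]], scans[[i]], mode = mode)$probe_set
        for (l in optode_labels(scans[[i]])) {
          if (l %in% aligned$points$label) {
            out <- c(out, dist3(point_of(aligned, l),
                                point_of(scans[[i]], l)))
          }
        }
      }
    }
  }
  out
}

oracle_inter_optode <- function(ps, channels) {
  out <- numeric(0)
  for (k in seq_len(nrow(channels))) {
    out <- c(out, dist3(point_of(ps, channels$source[k]),
                        point_of(ps, channels$detector[k])))
  }
  out
}

# textbook Welch two-sample t statistic and two-sided p-value
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = stat, p_value = 2 * pt(-abs(stat), df))
}

# uniformly random rotation from a random unit axis and angle
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2],
                -ax[3], 0, ax[1],
                ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_probe_set <- function(n = 8, fiducials = TRUE) {
  labs <- paste0(sample(c("S", "D"), n, replace = TRUE), seq_len(n))
  pts <- data.frame(label = labs,
                    x = runif(n, -100, 100),
                    y = runif(n, -100, 100),
                    z = runif(n, -50, 120))
  if (fiducials) {
    pts <- rbind(pts, data.frame(label = c("Nasion", "LPA", "RPA"),
                                 x = c(0, -75, 75),
                                 y = c(95, -5, 5) + rnorm(3),
                                 z = c(10, 0, 0) + rnorm(3)))
  }
  probe_set(pts, space = "scanner")
}

zero_noise_config <- function(seed = 11, ...) {
  cohort_config(cap_shift_sd = 0, cap_rotation_sd = 0,
                digitization_noise_sd = 0, fiducial_noise_sd = 0,
                circumference_sd = 0, seed = seed, ...)
}

pp_document <- function(ps) write_pp(ps)
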