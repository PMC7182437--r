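# shared fixtures and independent oracles (built in code, never stored)

tetrahedron_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# low-resolution template, built once per test run
cached_template <- local({
  tpl <- NULL
  function(n_phi = 16) {
    key <- as.character(n_phi)
    if (is.null(tpl[[key]])) tpl[[key]] <<- build_template(n_phi = n_phi)
    tpl[[key]]
  }
})

# brute-force point-to-triangle distance (oracle for the C++ kernel)
oracle_point_triangle <- function(p, a, b, cc) {
  # dense barycentric grid + edges/vertices; adequate as an independent
  # reference when compared at 1e-9 via the clamped closed form below
  e0 <- b - a; e1 <- cc - a; d <- a - p
  aa <- sum(e0 * e0); bb <- sum(e0 * e1); ccv <- sum(e1 * e1)
  dd <- sum(e0 * d); ee <- sum(e1 * d)
  det <- aa * ccv - bb * bb
  s <- bb * ee - ccv * dd; t <- bb * dd - aa * ee
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) {
        if (dd < 0) { s <- min(max(-dd / aa, 0), 1); t <- 0 }
        else { s <- 0; t <- min(max(-ee / ccv, 0), 1) }
      } else { s <- 0; t <- min(max(-ee / ccv, 0), 1) }
    } else if (t < 0) { t <- 0; s <- min(max(-dd / aa, 0), 1) }
    else { inv <- 1 / det; s <- s * inv; t <- t * inv }
  } else {
    if (s < 0) {
      tmp0 <- bb + dd; tmp1 <- ccv + ee
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        s <- min(max(num / (aa - 2 * bb + ccv), 0), 1); t <- 1 - s
      } else { s <- 0; t <- min(max(-ee / ccv, 0), 1) }
    } else if (t < 0) {
      tmp0 <- bb + ee; tmp1 <- aa + dd
      if (tmp1 > tmp0) {
        num <- tmp1 - tmp0
        t <- min(max(num / (aa - 2 * bb + ccv), 0), 1); s <- 1 - t
      } else { t <- 0; s <- min(max(-dd / aa, 0), 1) }
    } else {
      num <- ccv + ee - bb - dd
      s <- min(max(num / (aa - 2 * bb + ccv), 0), 1); t <- 1 - s
    }
  }
  q <- a + s * e0 + t * e1
  sqrt(sum((p - q)^2))
}

# exhaustive double-loop surface distance oracle
oracle_surface_distances <- function(ma, mb) {
  dir_d <- function(from, to) {
    vapply(seq_len(nrow(from$vertices)), function(i) {
      min(vapply(seq_len(nrow(to$faces)), function(j) {
        f <- to$faces[j, ]
        oracle_point_triangle(from$vertices[i, ], to$vertices[f[1], ],
                              to$vertices[f[2], ], to$vertices[f[3], ])
      }, numeric(1)))
    }, numeric(1))
  }
  dab <- dir_d(ma, mb); dba <- dir_d(mb, ma)
  c(hausdorff = max(max(dab), max(dba)), mean = mean(c(dab, dba)))
}

# exact rank-sum p by full enumeration (independent of the package code)
oracle_ranksum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  ws <- apply(utils::combn(n, na), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w + 1e-12), mean(ws >= w - 1e-12)))
}

# Spearman coefficient from the rank formula (average ranks)
oracle_spearman_c <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_rotation <- function() {
  ax <- rnorm(3)
  kneessm:::axis_angle_to_rot(ax / sqrt(sum(ax^2)), runif(1, 0, pi))
}

# landmark set of an idealised fully neutral knee (all angles zero)
neutral_landmarks <- function() {
  rbind(hip_center = c(0, 0, 400),
        knee_center_femur = c(0, 0, 4),
        knee_center_tibia = c(0, 0, -4),
        med_distal_condyle = c(-22, 0, 6),
        lat_distal_condyle = c(22, 0, 6),
        med_epicondyle = c(-38, 0, 16),
        lat_epicondyle = c(38, 0, 16),
        med_plateau = c(-30, 0, -3),
        lat_plateau = c(30, 0, -3),
        ant_plateau = c(0, 21, -3),
        post_plateau = c(0, -21, -3),
        ankle_center = c(0, 0, -360))
}
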