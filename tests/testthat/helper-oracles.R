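## Independent reference implementations used as oracles. These share no
## code with the package internals: the geometry oracle is a plain-R
## natural-extension-frame chain builder, the superposition oracle searches
## rotation space directly, and the energy oracle recomputes every term
## from first principles with dist().

.deg <- function(x) x * pi / 180

## --- reference internal-to-Cartesian builder -------------------------------
ref_nerf <- function(A, B, C, d, theta, tau) {
  th <- .deg(theta); ta <- .deg(tau)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-d * cos(th), d * sin(th) * cos(ta), d * sin(th) * sin(ta))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Returns list of L x 3 matrices N, CA, C, O, CEN
ref_build_backbone <- function(omega, phi, psi, cen_r) {
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.5
  L <- length(phi)
  N <- CA <- Cc <- O <- CEN <- matrix(0, L, 3)
  N[1, ] <- c(-b_n_ca, 0, 0)
  al <- .deg(180 - a_n_ca_c)
  Cc[1, ] <- b_ca_c * c(cos(al), sin(al), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      N[i, ]  <- ref_nerf(N[i - 1, ], CA[i - 1, ], Cc[i - 1, ], b_c_n,
                          a_ca_c_n, psi[i - 1])
      CA[i, ] <- ref_nerf(CA[i - 1, ], Cc[i - 1, ], N[i, ], b_n_ca,
                          a_c_n_ca, omega[i])
      Cc[i, ] <- ref_nerf(Cc[i - 1, ], N[i, ], CA[i, ], b_ca_c,
                          a_n_ca_c, phi[i])
    }
    O[i, ] <- ref_nerf(N[i, ], CA[i, ], Cc[i, ], b_c_o, a_ca_c_o,
                       psi[i] + 180)
    n1 <- N[i, ] - CA[i, ]; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- Cc[i, ] - CA[i, ]; n2 <- n2 / sqrt(sum(n2^2))
    u <- n1 + n2; u <- u / sqrt(sum(u^2))
    v <- c(n1[2] * n2[3] - n1[3] * n2[2],
           n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
    v <- v / sqrt(sum(v^2))
    g <- .deg(51.7)
    CEN[i, ] <- CA[i, ] + cen_r[i] * (-cos(g) * u + sin(g) * v)
  }
  list(N = N, CA = CA, C = Cc, O = O, CEN = CEN)
}

## Measure a torsion angle from four points (degrees, (-180, 180]).
ref_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  c2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(c1 * c2)
  y <- sum((c(c1[2] * c2[3] - c1[3] * c2[2], c1[3] * c2[1] - c1[1] * c2[3],
              c1[1] * c2[2] - c1[2] * c2[1])) * b2n)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## --- brute-force superposition oracle --------------------------------------
## Coarse rotation-grid search (Euler angles) refined by optim; independent
## of the SVD route.
ref_rmsd_grid <- function(a, b, step = 20) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((ac %*% t(rotmat(ang)) - bc)^2)))
  grid <- .deg(seq(0, 360 - step, by = step))
  best <- c(0, 0, 0); bv <- Inf
  for (z in grid) for (y in .deg(seq(0, 180, by = step))) for (x in grid) {
    v <- obj(c(z, y, x))
    if (v < bv) { bv <- v; best <- c(z, y, x) }
  }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

## --- reference energy terms -------------------------------------------------
ref_energy_terms <- function(st, phi, psi, ss) {
  L <- nrow(st$CA)
  coords <- rbind(st$N, st$CA, st$C, st$O, st$CEN)
  resid <- rep(seq_len(L), 5)
  D <- as.matrix(dist(coords))
  sep <- abs(outer(resid, resid, "-"))
  up <- upper.tri(D)
  steric <- sum(((4.0 - D)[up & sep >= 2 & D < 4.0])^2)
  cenD <- as.matrix(dist(st$CEN)); cup <- upper.tri(cenD)
  vdw <- -sum(cenD[cup] >= 4.5 & cenD[cup] <= 6.5)
  g <- rbind(st$CA, st$CEN)
  gm <- colMeans(g)
  rg <- sqrt(mean(rowSums(sweep(g, 2, gm)^2)))
  ONd <- sqrt(outer(rowSums(st$O^2), rowSums(st$N^2), "+") -
              2 * st$O %*% t(st$N))
  sepON <- abs(outer(seq_len(L), seq_len(L), "-"))
  hb <- -sum(ONd >= 2.6 & ONd <= 3.4 & sepON >= 3)
  obs <- ifelse(phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5, "H",
         ifelse(phi >= -180 & phi <= -60 & psi >= 60 & psi <= 180, "E", "L"))
  ssm <- sum(obs != strsplit(ss, "")[[1]])
  c(steric = steric, vdw_attract = vdw, rg = rg, hbond = hb, ss_pair = ssm)
}

## --- misc -------------------------------------------------------------------
ref_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

random_conformation <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conformation(random_sequence(L),
               cbind(omega = rep(180, L),
                     phi = stats::runif(L, -180, 180),
                     psi = stats::runif(L, -180, 180)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

toy_schedule <- function(base = c(30L, 30L, 30L, 60L), k3 = FALSE,
                         temperature = 2) {
  s <- default_schedules(base_cycles = base, temperature = temperature)
  if (k3) {
    s$abinitio <- stage_schedule(lapply(s$abinitio,
                                        function(x) { x$k <- 3L; x }))
    s$evolutionary <- stage_schedule(lapply(s$evolutionary,
                                            function(x) { x$k <- 3L; x }))
  }
  s
}
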