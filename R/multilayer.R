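# Layered-media solvers for the chamber stack (bath / slide / sample /
# coverslip / backing).
#
# Conventions: time dependence exp(+i omega t), propagation along +z, z = 0
# at the first interface. Amplitudes are complex pressure amplitudes relative
# to an incident wave of unit amplitude. Each layer's amplitudes are
# referenced at its top interface (the first half-space at the first
# interface, the final half-space at the last). Complex wavenumbers
# k = omega/c - i alpha(f) carry attenuation; the radiation condition forces
# the backward amplitude in the final half-space to zero.

vert_wavenumber <- function(k, kx) {
  # vertical wavenumber branch: decaying (Im <= 0) or outgoing (Re >= 0)
  nu <- sqrt(as.complex(k^2 - kx^2))
  flip <- Im(nu) > 0 | (Im(nu) == 0 & Re(nu) < 0)
  nu[flip] <- -nu[flip]
  nu
}

#' Build a layered stack
#'
#' An ordered sequence of media with thicknesses; the first and last entries
#' are half-spaces (`Inf` thickness). Zero-thickness interior layers are
#' silently dropped (they are physically absent and the solvers' limits
#' agree).
#'
#' @param media A list of [acoustic_medium()] objects.
#' @param thickness Thicknesses in m, same length as `media`; `Inf` for the
#'   two half-spaces.
#' @return An object of class `layer_stack`.
#' @examples
#' mats <- sono_materials()
#' layer_stack(
#'   list(material(mats, "water"), material(mats, "glass"),
#'        material(mats, "water"), material(mats, "glass"),
#'        material(mats, "air")),
#'   c(Inf, 1.2e-3, 15e-6, 0.17e-3, Inf)
#' )
#' @export
layer_stack <- function(media, thickness) {
  if (inherits(media, "acoustic_medium")) media <- list(media)
  stopifnot(is.list(media), all(vapply(media, inherits, logical(1), "acoustic_medium")))
  thickness <- as.double(thickness)
  if (length(media) != length(thickness)) {
    stop("`media` and `thickness` must have the same length", call. = FALSE)
  }
  if (length(media) < 2) stop("a stack needs at least two half-spaces", call. = FALSE)
  n <- length(media)
  if (!is.infinite(thickness[1]) || !is.infinite(thickness[n])) {
    stop("first and last layers must be half-spaces (thickness = Inf)", call. = FALSE)
  }
  if (n > 2 && any(is.infinite(thickness[2:(n - 1)]))) {
    stop("only the first and last layers may be half-spaces", call. = FALSE)
  }
  keep <- c(TRUE, thickness[-c(1, n)] > 0, TRUE)
  if (n > 2 && any(thickness[2:(n - 1)] < 0)) {
    stop("interior thicknesses must be >= 0", call. = FALSE)
  }
  media <- media[keep]
  thickness <- thickness[keep]
  structure(list(media = media, thickness = thickness), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  n <- length(x$media)
  cat("<layer_stack> ", n, " layers\n", sep = "")
  for (i in seq_len(n)) {
    th <- if (is.infinite(x$thickness[i])) "half-space"
          else sprintf("%g um", x$thickness[i] * 1e6)
    cat(sprintf("  [%d] %-14s %s\n", i, x$media[[i]]$name, th))
  }
  invisible(x)
}

#' Reverse a stack
#'
#' Swaps the direction of incidence; by reciprocity a lossless stack
#' transmits the same power either way.
#'
#' @param stack A [layer_stack()].
#' @return The reversed `layer_stack`.
#' @export
reverse_stack <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  layer_stack(rev(stack$media), rev(stack$thickness))
}

#' Read a stack description file
#'
#' Parses a YAML list of `{material: name, thickness_um: number | "inf"}`
#' entries and resolves the material names against a registry.
#'
#' @param path Path to the YAML stack description.
#' @param materials A `sono_materials` registry (default the shipped table).
#' @return A [layer_stack()].
#' @export
stack_from_config <- function(path, materials = sono_materials()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || length(cfg) < 2) {
    stop("stack config must list at least two layers", call. = FALSE)
  }
  media <- lapply(cfg, function(l) material(materials, l$material))
  th <- vapply(cfg, function(l) {
    t <- l$thickness_um
    if (identical(t, "inf") || is.infinite(as.numeric(t))) Inf
    else as.numeric(t) * 1e-6
  }, numeric(1))
  layer_stack(media, th)
}

# complex wavenumber with attenuation for the longitudinal branch
long_wavenumber <- function(medium, f) {
  2 * pi * f / medium$c_long - 1i * attenuation_at(medium, f)
}

# ---------------------------------------------------------------------------
# Normal incidence: 2x2 transfer-matrix chain (all media fluid-modelled with
# their longitudinal properties; mode conversion vanishes at normal
# incidence).

fluid_chain_solve <- function(rho, kz, omega, d) {
  N <- length(rho)
  Z <- omega * rho / kz
  A <- B <- complex(N)
  Ms <- vector("list", N)
  Mtot <- diag(2) + 0i
  if (N > 2) {
    for (j in 2:(N - 1)) {
      kd <- kz[j] * d[j]
      Ms[[j]] <- matrix(c(cos(kd), 1i * sin(kd) / Z[j],
                          1i * Z[j] * sin(kd), cos(kd)), 2, 2)
      Mtot <- Mtot %*% Ms[[j]]
    }
  }
  denom <- Mtot[1, 1] + Mtot[1, 2] / Z[N] + Z[1] * (Mtot[2, 1] + Mtot[2, 2] / Z[N])
  t <- 2 / denom
  r <- t * (Mtot[1, 1] + Mtot[1, 2] / Z[N]) - 1
  A[1] <- 1 + 0i; B[1] <- r
  A[N] <- t; B[N] <- 0 + 0i
  if (N > 2) {
    S <- c(t, t / Z[N]) # state (p, v) at the last interface
    for (j in (N - 1):2) {
      S <- as.vector(Ms[[j]] %*% S) # state at layer j's top interface
      A[j] <- (S[1] + Z[j] * S[2]) / 2
      B[j] <- (S[1] - Z[j] * S[2]) / 2
    }
  }
  Tp <- Mod(t)^2 * Re(1 / Conj(Z[N])) / Re(1 / Conj(Z[1]))
  list(A = A, B = B, r = r, t = t, Z = Z,
       T_power = Tp, R_power = Mod(r)^2)
}

make_layer_field <- function(stack, f, theta_i, kx, pars, phi, psi, r, t,
                             T_power, R_power, method) {
  omega <- 2 * pi * f
  n <- length(stack$media)
  layers <- tibble::tibble(
    layer = seq_len(n),
    material = vapply(stack$media, function(m) m$name, character(1)),
    thickness = stack$thickness,
    fluid = vapply(stack$media, is_fluid, logical(1)),
    p_down = vapply(seq_len(n), function(j) pars[[j]]$rho * omega^2 * phi[[j]][1], complex(1)),
    p_up = vapply(seq_len(n), function(j) pars[[j]]$rho * omega^2 * phi[[j]][2], complex(1)),
    psi_down = vapply(seq_len(n), function(j) psi[[j]][1], complex(1)),
    psi_up = vapply(seq_len(n), function(j) psi[[j]][2], complex(1))
  )
  structure(
    list(stack = stack, f = f, theta_i = theta_i, omega = omega, kx = kx,
         pars = pars, phi = phi, psi = psi, layers = layers,
         p_r = r, p_t = t, T_power = T_power, R_power = R_power,
         method = method),
    class = "layer_field"
  )
}

#' Solve a layered stack at normal incidence
#'
#' Chains 2x2 transfer matrices (pressure and normal-velocity continuity at
#' every interface) with complex wavenumbers `k = omega/c - i alpha(f)`.
#' Solids are propagated with their longitudinal properties; at normal
#' incidence no mode conversion occurs.
#'
#' @param stack A [layer_stack()].
#' @param f Frequency in Hz (> 0).
#' @return A `layer_field` object holding per-layer complex forward/backward
#'   pressure amplitudes, the overall pressure reflection `p_r` and
#'   transmission `p_t`, and power fractions `T_power`, `R_power`.
#' @examples
#' mats <- sono_materials()
#' st <- layer_stack(list(material(mats, "water"), material(mats, "glass")),
#'                   c(Inf, Inf))
#' solve_normal(st, 1e6)$T_power
#' @export
solve_normal <- function(stack, f) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("f must be > 0", call. = FALSE)
  media <- stack$media
  n <- length(media)
  omega <- 2 * pi * f
  kz <- vapply(media, long_wavenumber, complex(1), f = f)
  rho <- vapply(media, function(m) m$density, numeric(1))
  sol <- fluid_chain_solve(rho, kz, omega, stack$thickness)
  pars <- lapply(seq_len(n), function(j) {
    list(rho = rho[j], nu_p = kz[j], nu_s = NA_complex_, mu = 0 + 0i, fluid = TRUE)
  })
  phi <- lapply(seq_len(n), function(j) c(sol$A[j], sol$B[j]) / (rho[j] * omega^2))
  psi <- rep(list(c(0 + 0i, 0 + 0i)), n)
  make_layer_field(stack, f, 0, 0, pars, phi, psi,
                   r = sol$r, t = sol$t,
                   T_power = sol$T_power, R_power = sol$R_power,
                   method = "transfer_matrix")
}

# fluid-only oblique transfer matrix: independent implementation used as the
# oracle for the global-matrix solver on all-fluid stacks
fluid_oblique_tm <- function(stack, f, theta_i) {
  media <- stack$media
  omega <- 2 * pi * f
  c1 <- media[[1]]$c_long
  kx <- omega * sin(deg2rad(theta_i)) / c1
  k <- vapply(media, long_wavenumber, complex(1), f = f)
  nu <- vert_wavenumber(k, kx)
  rho <- vapply(media, function(m) m$density, numeric(1))
  sol <- fluid_chain_solve(rho, nu, omega, stack$thickness)
  list(r = sol$r, t = sol$t, T_power = sol$T_power, R_power = sol$R_power,
       A = sol$A, B = sol$B)
}

# ---------------------------------------------------------------------------
# Oblique incidence: global-matrix solution with longitudinal and vertically
# polarized shear waves in solid layers. Displacement potentials phi (P) and
# psi (SV): u = grad(phi) + curl((0, psi, 0)); the lateral wavenumber kx is
# conserved across layers (Snell).

layer_pars_oblique <- function(media, f, kx) {
  omega <- 2 * pi * f
  lapply(media, function(m) {
    kp <- long_wavenumber(m, f)
    if (is_fluid(m)) {
      list(rho = m$density, nu_p = vert_wavenumber(kp, kx),
           nu_s = NA_complex_, mu = 0 + 0i, fluid = TRUE)
    } else {
      # shear branch reuses the medium's attenuation law
      ks <- omega / m$c_shear - 1i * attenuation_at(m, f)
      list(rho = m$density, nu_p = vert_wavenumber(kp, kx),
           nu_s = vert_wavenumber(ks, kx),
           mu = m$density * omega^2 / ks^2, fluid = FALSE)
    }
  })
}

# rows: (u_x, u_z, sigma_zz, sigma_xz) as linear functions of the wave
# amplitudes named in `types` ("Pd","Pu","Sd","Su"); zeta is the local depth
wave_cols <- function(par, zeta, kx, omega, types) {
  vapply(types, function(tp) {
    sgn <- if (tp %in% c("Pu", "Su")) 1 else -1
    if (substr(tp, 1, 1) == "P") {
      E <- exp(sgn * 1i * par$nu_p * zeta)
      dE <- sgn * 1i * par$nu_p * E
      c(-1i * kx * E, dE,
        (2 * par$mu * kx^2 - par$rho * omega^2) * E,
        -2i * par$mu * kx * dE)
    } else {
      E <- exp(sgn * 1i * par$nu_s * zeta)
      dE <- sgn * 1i * par$nu_s * E
      c(-dE, -1i * kx * E,
        -2i * par$mu * kx * dE,
        par$mu * (par$nu_s^2 - kx^2) * E)
    }
  }, complex(4))
}

# time-averaged normal energy flux -1/2 Re(szz vz* + sxz vx*) of the waves in
# `amps` (list with phi_down, phi_up, psi_down, psi_up) at local depth zeta
flux_at <- function(par, amps, zeta, kx, omega) {
  types <- c("Pd", "Pu")
  vals <- c(amps$phi_down, amps$phi_up)
  if (!par$fluid) {
    types <- c(types, "Sd", "Su")
    vals <- c(vals, amps$psi_down, amps$psi_up)
  }
  F <- as.vector(wave_cols(par, zeta, kx, omega, types) %*% vals)
  vx <- 1i * omega * F[1]
  vz <- 1i * omega * F[2]
  -0.5 * Re(F[3] * Conj(vz) + F[4] * Conj(vx))
}

oblique_types <- function(pars, i, n) {
  if (i == 1) return("Pu")
  if (i == n) {
    if (pars[[i]]$fluid) return("Pd") else return(c("Pd", "Sd"))
  }
  if (pars[[i]]$fluid) c("Pd", "Pu") else c("Pd", "Pu", "Sd", "Su")
}

#' Solve a layered stack at oblique incidence
#'
#' Global-matrix solution with longitudinal and vertically polarized shear
#' waves in solid layers (fluid layers carry longitudinal waves only). The
#' lateral wavenumber is conserved across layers; boundary conditions are
#' continuity of normal displacement and normal stress everywhere, tangential
#' displacement and shear stress at solid-solid interfaces, and vanishing
#' shear stress where a solid meets a fluid. Angles beyond the longitudinal
#' critical angle are supported (transmission continues via the shear branch
#' or evanescent tunnelling through thin layers). Reduces to [solve_normal()]
#' at `theta_i = 0`.
#'
#' @param stack A [layer_stack()] whose first layer is fluid.
#' @param f Frequency in Hz (> 0).
#' @param theta_i Incidence angle in degrees, `[0, 90)`.
#' @return A `layer_field` object (see [solve_normal()]); in solid layers the
#'   backward/forward entries hold the compressional pressure-equivalent
#'   amplitudes and the shear potential amplitudes.
#' @export
solve_oblique <- function(stack, f, theta_i) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("f must be > 0", call. = FALSE)
  if (!is.numeric(theta_i) || length(theta_i) != 1L || theta_i < 0 || theta_i >= 90) {
    stop("theta_i must be in [0, 90) degrees", call. = FALSE)
  }
  if (!is_fluid(stack$media[[1]])) {
    stop("the incident half-space must be fluid", call. = FALSE)
  }
  out <- try(solve_oblique_once(stack, f, theta_i), silent = TRUE)
  if (inherits(out, "try-error")) {
    # isolated layer-resonance poles: re-solve with a small angle nudge
    warning("near-singular global matrix at theta_i = ", theta_i,
            " deg; re-solved with a 1e-6 degree nudge", call. = FALSE)
    out <- solve_oblique_once(stack, f, theta_i + 1e-6)
    out$theta_i <- theta_i
  }
  out
}

solve_oblique_once <- function(stack, f, theta_i) {
  media <- stack$media
  n <- length(media)
  d <- stack$thickness
  omega <- 2 * pi * f
  kx <- omega * sin(deg2rad(theta_i)) / media[[1]]$c_long
  pars <- layer_pars_oblique(media, f, kx)
  types <- lapply(seq_len(n), function(i) oblique_types(pars, i, n))
  n_unk <- sum(lengths(types))
  col0 <- cumsum(c(0, lengths(types)))
  G <- matrix(0 + 0i, n_unk, n_unk)
  rhs <- complex(n_unk)
  A_inc <- 1 / (pars[[1]]$rho * omega^2) # potential amplitude of unit pressure
  row <- 0L
  for (m in seq_len(n - 1)) {
    i <- m
    fa <- pars[[i]]$fluid
    fb <- pars[[i + 1]]$fluid
    rows_sel <- if (fa && fb) c(2L, 3L) else if (fa || fb) c(2L, 3L, 4L) else 1:4
    zeta_a <- if (i == 1) 0 else d[i]
    Fa <- wave_cols(pars[[i]], zeta_a, kx, omega, types[[i]])
    Fb <- wave_cols(pars[[i + 1]], 0, kx, omega, types[[i + 1]])
    rr <- row + seq_along(rows_sel)
    G[rr, (col0[i] + 1):col0[i + 1]] <- Fa[rows_sel, , drop = FALSE]
    G[rr, (col0[i + 1] + 1):col0[i + 2]] <- -Fb[rows_sel, , drop = FALSE]
    if (m == 1) {
      Finc <- wave_cols(pars[[1]], 0, kx, omega, "Pd")
      rhs[rr] <- -A_inc * Finc[rows_sel, 1]
    }
    row <- row + length(rows_sel)
  }
  stopifnot(row == n_unk)
  # two-sided equilibration: displacement and stress rows differ by ~rho
  # omega^2 in magnitude, which would otherwise wreck the conditioning
  rs <- apply(abs(G), 1, max)
  rs[rs == 0] <- 1
  G <- G / rs
  rhs <- rhs / rs
  cs <- apply(abs(G), 2, max)
  cs[cs == 0] <- 1
  G <- sweep(G, 2, cs, "/")
  a <- solve(G, rhs) / cs
  phi <- rep(list(c(0 + 0i, 0 + 0i)), n)
  psi <- rep(list(c(0 + 0i, 0 + 0i)), n)
  for (i in seq_len(n)) {
    vals <- a[(col0[i] + 1):col0[i + 1]]
    names(vals) <- types[[i]]
    phi[[i]] <- c(if ("Pd" %in% types[[i]]) vals[["Pd"]] else 0 + 0i,
                  if ("Pu" %in% types[[i]]) vals[["Pu"]] else 0 + 0i)
    psi[[i]] <- c(if ("Sd" %in% types[[i]]) vals[["Sd"]] else 0 + 0i,
                  if ("Su" %in% types[[i]]) vals[["Su"]] else 0 + 0i)
  }
  phi[[1]][1] <- A_inc
  p_r <- pars[[1]]$rho * omega^2 * phi[[1]][2]
  p_t <- if (pars[[n]]$fluid) pars[[n]]$rho * omega^2 * phi[[n]][1] else NA_complex_
  I_inc <- flux_at(pars[[1]], list(phi_down = A_inc, phi_up = 0 + 0i,
                                   psi_down = 0 + 0i, psi_up = 0 + 0i),
                   0, kx, omega)
  I_tr <- flux_at(pars[[n]], list(phi_down = phi[[n]][1], phi_up = 0 + 0i,
                                  psi_down = psi[[n]][1], psi_up = 0 + 0i),
                  0, kx, omega)
  make_layer_field(stack, f, theta_i, kx, pars, phi, psi,
                   r = p_r, t = p_t,
                   T_power = I_tr / I_inc, R_power = Mod(p_r)^2,
                   method = "global_matrix")
}

# ---------------------------------------------------------------------------
# Brute-force five-layer oracle: assembles the full boundary-condition linear
# system in the named wave amplitudes (p_r, p_a ... p_t given p_i = 1).
# Normal incidence, fluid-modelled; used to cross-check the transfer-matrix
# path in tests.

#' Brute-force five-layer solver (test oracle)
#'
#' Solves the eight-unknown linear system (reflected wave, the three interior
#' layers' forward/backward waves, and the transmitted wave) obtained from
#' pressure and normal-velocity continuity at the four interfaces of a
#' five-layer stack at normal incidence, all media fluid-modelled. This is an
#' independent check of [solve_normal()], not an efficient solver.
#'
#' @param stack A five-layer [layer_stack()].
#' @param f Frequency in Hz.
#' @return A `layer_field` object.
#' @export
brute_force_five_layer <- function(stack, f) {
  stopifnot(inherits(stack, "layer_stack"))
  media <- stack$media
  n <- length(media)
  if (n != 5) stop("brute_force_five_layer needs exactly 5 layers", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("f must be > 0", call. = FALSE)
  omega <- 2 * pi * f
  k <- vapply(media, long_wavenumber, complex(1), f = f)
  rho <- vapply(media, function(m) m$density, numeric(1))
  Z <- omega * rho / k
  d <- stack$thickness
  # unknowns: (p_r, p_a, p_b, p_c, p_d, p_e, p_f, p_t)
  G <- matrix(0 + 0i, 8, 8)
  rhs <- complex(8)
  dn <- function(j, row_p, row_v, cols) {
    # contributions of layer j (amplitudes referenced at its top) evaluated
    # at its bottom interface
    ph <- exp(c(-1i, 1i) * k[j] * d[j])
    G[row_p, cols] <<- G[row_p, cols] + c(ph[1], ph[2])
    G[row_v, cols] <<- G[row_v, cols] + c(ph[1], -ph[2]) / Z[j]
  }
  # interface 1 (z = 0): layer 1 vs layer 2
  # pressure: 1 + p_r = p_a + p_b ; velocity: (1 - p_r)/Z1 = (p_a - p_b)/Z2
  G[1, 1] <- 1 + 0i;      G[1, 2:3] <- c(-1, -1)
  G[2, 1] <- -1 / Z[1];   G[2, 2:3] <- c(-1, 1) / Z[2]
  rhs[1] <- -1
  rhs[2] <- -1 / Z[1]
  # interface 2: layer 2 (bottom) vs layer 3 (top)
  dn(2, 3, 4, 2:3)
  G[3, 4:5] <- G[3, 4:5] - c(1, 1)
  G[4, 4:5] <- G[4, 4:5] - c(1, -1) / Z[3]
  # interface 3: layer 3 (bottom) vs layer 4 (top)
  dn(3, 5, 6, 4:5)
  G[5, 6:7] <- G[5, 6:7] - c(1, 1)
  G[6, 6:7] <- G[6, 6:7] - c(1, -1) / Z[4]
  # interface 4: layer 4 (bottom) vs layer 5 (top, transmitted only)
  dn(4, 7, 8, 6:7)
  G[7, 8] <- -1
  G[8, 8] <- -1 / Z[5]
  x <- tryCatch(solve(G, rhs), error = function(e) {
    qrG <- qr(G)
    bad <- ceiling(qrG$pivot[qr(G)$rank + 1] / 2)
    stop("singular boundary-condition system near interface ", min(bad, 4),
         call. = FALSE)
  })
  A <- c(1 + 0i, x[2], x[4], x[6], x[8])
  B <- c(x[1], x[3], x[5], x[7], 0 + 0i)
  pars <- lapply(seq_len(5), function(j) {
    list(rho = rho[j], nu_p = k[j], nu_s = NA_complex_, mu = 0 + 0i, fluid = TRUE)
  })
  phi <- lapply(seq_len(5), function(j) c(A[j], B[j]) / (rho[j] * omega^2))
  psi <- rep(list(c(0 + 0i, 0 + 0i)), 5)
  Tp <- Mod(x[8])^2 * Re(1 / Conj(Z[5])) / Re(1 / Conj(Z[1]))
  make_layer_field(stack, f, 0, 0, pars, psi = psi, phi = phi,
                   r = x[1], t = x[8],
                   T_power = Tp, R_power = Mod(x[1])^2,
                   method = "brute_force")
}

# ---------------------------------------------------------------------------

#' Pressure magnitude inside one layer
#'
#' Evaluates `|p|` (for solids, the magnitude of the normal stress) on a grid
#' of local depths within a layer of a solved field.
#'
#' @param field A `layer_field` from [solve_normal()] or [solve_oblique()].
#' @param layer Layer index.
#' @param zeta Local depths in m measured from the layer's top interface
#'   (default a 201-point grid across the layer).
#' @return A tibble with `zeta` and `p_abs` (relative to unit incidence).
#' @export
layer_pressure <- function(field, layer, zeta = NULL) {
  stopifnot(inherits(field, "layer_field"))
  n <- length(field$stack$media)
  stopifnot(layer >= 1, layer <= n)
  d <- field$stack$thickness[layer]
  if (is.null(zeta)) {
    zeta <- if (is.infinite(d)) seq(0, 2 * pi / Re(field$pars[[layer]]$nu_p), length.out = 201)
            else seq(0, d, length.out = 201)
    if (layer == 1) zeta <- -rev(zeta)
  }
  par <- field$pars[[layer]]
  ph <- field$phi[[layer]]
  ps <- field$psi[[layer]]
  omega <- field$omega
  kx <- field$kx
  Phi <- ph[1] * exp(-1i * par$nu_p * zeta) + ph[2] * exp(1i * par$nu_p * zeta)
  szz <- (2 * par$mu * kx^2 - par$rho * omega^2) * Phi
  if (!par$fluid && (ps[1] != 0 || ps[2] != 0)) {
    dPsi <- -1i * par$nu_s * ps[1] * exp(-1i * par$nu_s * zeta) +
      1i * par$nu_s * ps[2] * exp(1i * par$nu_s * zeta)
    szz <- szz - 2i * par$mu * kx * dPsi
  }
  tibble::tibble(zeta = zeta, p_abs = Mod(szz))
}

#' Pressure profile across a solved stack
#'
#' @param field A `layer_field`.
#' @param n_per_layer Sample points per interior layer.
#' @param pad Depth shown into each half-space, m (default one wavelength).
#' @return A tibble with global depth `z` (m, 0 at the first interface),
#'   `layer`, `material` and `p_abs`.
#' @export
pressure_profile <- function(field, n_per_layer = 101, pad = NULL) {
  stopifnot(inherits(field, "layer_field"))
  st <- field$stack
  n <- length(st$media)
  ztop <- c(0, cumsum(ifelse(is.finite(st$thickness), st$thickness, 0)))[seq_len(n)]
  purrr::map_dfr(seq_len(n), function(j) {
    d <- st$thickness[j]
    if (is.infinite(d)) {
      lambda <- 2 * pi / abs(Re(field$pars[[j]]$nu_p) + 1e-300)
      p <- if (is.null(pad)) min(lambda, 5e-3) else pad
      zeta <- seq(0, p, length.out = n_per_layer)
      if (j == 1) zeta <- -rev(zeta)
    } else {
      zeta <- seq(0, d, length.out = n_per_layer)
    }
    lp <- layer_pressure(field, j, zeta)
    tibble::tibble(z = ztop[j] + lp$zeta, layer = j,
                   material = st$media[[j]]$name, p_abs = lp$p_abs)
  })
}

#' @export
print.layer_field <- function(x, ...) {
  cat(sprintf("<layer_field> %d layers, f = %g MHz, theta_i = %g deg (%s)\n",
              length(x$stack$media), x$f / 1e6, x$theta_i, x$method))
  cat(sprintf("  |p_r| = %.6g  |p_t| = %.6g  T_power = %.6g  R_power = %.6g\n",
              Mod(x$p_r), Mod(x$p_t), x$T_power, x$R_power))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-layer amplitudes of a solved field
#'
#' @param x A `layer_field`.
#' @param ... Ignored.
#' @return A tibble with one row per layer: material, thickness and the
#'   magnitudes of the forward/backward compressional pressure amplitudes and
#'   shear-potential amplitudes.
#' @exportS3Method generics::tidy
tidy.layer_field <- function(x, ...) {
  dplyr::mutate(
    x$layers,
    p_down_abs = Mod(.data$p_down), p_up_abs = Mod(.data$p_up),
    psi_down_abs = Mod(.data$psi_down), psi_up_abs = Mod(.data$psi_up)
  ) |>
    dplyr::select("layer", "material", "thickness", "fluid",
                  "p_down_abs", "p_up_abs", "psi_down_abs", "psi_up_abs")
}

#' One-row summary of a solved field
#'
#' @param x A `layer_field`.
#' @param ... Ignored.
#' @return A one-row tibble: frequency, incidence angle, reflected and
#'   transmitted pressure magnitudes and power fractions.
#' @exportS3Method generics::glance
glance.layer_field <- function(x, ...) {
  tibble::tibble(
    f_hz = x$f, theta_i_deg = x$theta_i,
    p_r_abs = Mod(x$p_r), p_t_abs = Mod(x$p_t),
    T_power = x$T_power, R_power = x$R_power
  )
}

#' Plot the pressure magnitude across a solved stack
#'
#' @param object A `layer_field`.
#' @param ... Passed to [pressure_profile()].
#' @return A ggplot of `|p|` versus depth with interfaces marked.
#' @exportS3Method ggplot2::autoplot
autoplot.layer_field <- function(object, ...) {
  prof <- pressure_profile(object, ...)
  st <- object$stack
  zint <- c(0, cumsum(st$thickness[is.finite(st$thickness)]))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z * 1e3, y = .data$p_abs)) +
    ggplot2::geom_vline(xintercept = zint * 1e3, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth z (mm)", y = "|p| / |p_i|",
                  title = sprintf("Layered field at %g MHz, %g deg",
                                  object$f / 1e6, object$theta_i))
}

# ---------------------------------------------------------------------------

#' Standing-wave amplitude versus sample gap
#'
#' Rebuilds the stack for each gap `L`, solves it, and reports the peak
#' pressure magnitude inside the (fluid) sample layer relative to the
#' incident amplitude. Interference between the forward and reflected waves
#' inside the thin gap makes this periodic in `L` with period half the
#' sample wavelength (lossless, normal incidence).
#'
#' @param stack A [layer_stack()] whose swept (sample) layer is interior.
#' @param gaps Gap thicknesses L in m (non-empty).
#' @param f Frequency in Hz.
#' @param theta_i Incidence angle in degrees (0 = normal).
#' @param sample_index Index of the swept layer (default the middle layer).
#' @param n_z Depth samples used for the in-layer peak search.
#' @return A tibble of class `gap_sweep` with columns `L` (m) and
#'   `amplitude_ratio`.
#' @export
sample_amplitude_vs_gap <- function(stack, gaps, f, theta_i = 0,
                                    sample_index = NULL, n_z = 201) {
  stopifnot(inherits(stack, "layer_stack"))
  if (length(gaps) == 0) stop("gap_range must be non-empty", call. = FALSE)
  n <- length(stack$media)
  if (is.null(sample_index)) sample_index <- (n + 1L) %/% 2L
  if (sample_index <= 1 || sample_index >= n) {
    stop("the swept sample layer must be interior", call. = FALSE)
  }
  if (!is_fluid(stack$media[[sample_index]])) {
    stop("the swept sample layer must be fluid", call. = FALSE)
  }
  amp <- vapply(gaps, function(L) {
    th <- stack$thickness
    th[sample_index] <- L
    st <- layer_stack(stack$media, th)
    fld <- if (theta_i == 0) solve_normal(st, f) else solve_oblique(st, f, theta_i)
    if (L <= 0) return(NA_real_)
    fluid_layer_peak(fld, sample_index, L, n_z)
  }, numeric(1))
  out <- tibble::tibble(L = gaps, amplitude_ratio = amp)
  attr(out, "f") <- f
  attr(out, "theta_i") <- theta_i
  class(out) <- c("gap_sweep", class(out))
  out
}

#' Plot a gap sweep
#'
#' @param object A `gap_sweep` tibble from [sample_amplitude_vs_gap()].
#' @param ... Ignored.
#' @return A ggplot of peak sample amplitude versus gap.
#' @exportS3Method ggplot2::autoplot
autoplot.gap_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L * 1e6, y = .data$amplitude_ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gap L (um)", y = "peak |p| / |p_i|",
                  title = "Sample-layer standing-wave amplitude vs gap")
}

# exact peak |p| of a fluid layer's standing wave over local depth [0, L];
# for a real vertical wavenumber |p|^2 = |A|^2 + |B|^2 + 2|AB*|cos(...) and
# the cosine's extremum over the interval is found analytically, otherwise a
# dense grid is used
fluid_layer_peak <- function(field, j, L, n_z = 501) {
  par <- field$pars[[j]]
  scale <- par$rho * field$omega^2
  A <- scale * field$phi[[j]][1]
  B <- scale * field$phi[[j]][2]
  nu <- par$nu_p
  if (par$fluid && abs(Im(nu)) < 1e-12 * abs(Re(nu))) {
    cross <- A * Conj(B)
    amp <- Mod(cross)
    ph <- Arg(cross)
    lo <- ph - 2 * Re(nu) * L
    peak_cos <- if (floor(ph / (2 * pi)) >= ceiling(lo / (2 * pi))) 1
                else max(cos(lo), cos(ph))
    sqrt(max(Mod(A)^2 + Mod(B)^2 + 2 * amp * peak_cos, 0))
  } else {
    max(layer_pressure(field, j, seq(0, L, length.out = n_z))$p_abs)
  }
}

#' Power lost to attenuation over a path
#'
#' `1 - exp(-2 alpha(f) d)`: power attenuates at twice the amplitude rate.
#'
#' @param medium An [acoustic_medium()].
#' @param d Path length in m (>= 0); vectorized.
#' @param f Frequency in Hz.
#' @return Fraction of power lost, in `[0, 1]`.
#' @examples
#' mats <- sono_materials()
#' power_loss_through(material(mats, "glass"), 10e-3, 1e6) # <= 5%
#' @export
power_loss_through <- function(medium, d, f) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  1 - exp(-2 * attenuation_at(medium, f) * d)
}

#' Seeded random stack generator
#'
#' Deterministic fixture generator for property tests: media with impedances
#' spanning more than three orders of magnitude (densities 1e2-1e4 kg/m^3,
#' speeds 300-6000 m/s), interior thicknesses log-uniform over 10 um-10 mm.
#' The global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_layers Number of layers (>= 2), including the two half-spaces.
#' @param lossy Draw non-zero attenuation coefficients?
#' @return A [layer_stack()] of fluid-modelled media.
#' @export
generate_random_stack <- function(seed, n_layers, lossy = FALSE) {
  stopifnot(n_layers >= 2)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  media <- lapply(seq_len(n_layers), function(i) {
    acoustic_medium(
      name = paste0("m", i),
      density = 10^stats::runif(1, 2, 4),
      c_long = stats::runif(1, 300, 6000),
      alpha0_db_per_cm = if (lossy) stats::runif(1, 0, 1) else 0
    )
  })
  th <- c(Inf, 10^stats::runif(max(n_layers - 2, 0), -5, -2), Inf)
  layer_stack(media, th)
}
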