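# Independent reference implementations used as oracles. They deliberately
# share no code with the package: the diffusion oracle is a per-cell double
# loop, the ODE oracle is a hand-written fixed-step RK4 on the reduced
# right-hand side.

ref_diffuse <- function(v, ce, cd, neighborhood = "von_neumann",
                        boundary = "torus", mode = "normalized",
                        clamp = FALSE) {
  H <- nrow(v)
  W <- ncol(v)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (neighborhood == "moore") {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  cd_eff <- if (mode == "normalized") cd / length(offs) else cd
  out <- matrix(0, H, W)
  for (yy in seq_len(H)) {
    for (xx in seq_len(W)) {
      s <- 0
      for (o in offs) {
        nx <- xx + o[1]
        ny <- yy + o[2]
        nv <- if (boundary == "torus") {
          v[((ny - 1) %% H) + 1, ((nx - 1) %% W) + 1]
        } else if (nx < 1 || nx > W || ny < 1 || ny > H) {
          v[yy, xx]
        } else {
          v[ny, nx]
        }
        s <- s + (nv - v[yy, xx])
      }
      out[yy, xx] <- ce * (v[yy, xx] + cd_eff * s)
    }
  }
  if (clamp) out <- pmax(out, 0)
  out
}

# Fixed-step classical RK4 on the six reduced ODEs, written directly from
# the rate laws.
rk4_reduced <- function(p, inputs, horizon, h) {
  f <- function(y) c(
    p$ka1 * inputs[1] - p$kd * y[1],
    p$ka2 * inputs[2] * inputs[3] / p$bilinear_scale - p$kd * y[2],
    p$ka3 * inputs[2] / (1 + inputs[3] / p$Ki) - p$kd * y[3],
    p$ks1 * y[1], p$ks2 * y[2], p$ks3 * y[3])
  y <- numeric(6)
  for (i in seq_len(round(horizon / h))) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(y) <- c("A_Th1", "A_Th17", "A_Treg", "IFNg", "IL17", "IL10")
  y
}

# Closed-form solution of the Th1 branch for constant input c:
#   A(T) = (ka1 c / kd)(1 - exp(-kd T))
#   IFNg(T) = ks1 (ka1 c / kd)(T - (1 - exp(-kd T)) / kd)
closed_form_th1 <- function(p, c, horizon) {
  A_inf <- p$ka1 * c / p$kd
  A <- A_inf * (1 - exp(-p$kd * horizon))
  I <- p$ks1 * A_inf * (horizon - (1 - exp(-p$kd * horizon)) / p$kd)
  c(A_Th1 = A, IFNg = I)
}

# Down-scaled scenario with the reference biology for fast engine tests:
# same rules and layers, smaller grid and populations.
small_scenario <- function(seed = 1L, cycles = 10L, grid = c(20L, 20L),
                           n_bact = 30L, n_tcell = 80L, n_dc = 80L, ...) {
  scenario_config(
    grid = grid,
    populations = list(
      list(type = "bacterium", state = "infectious", count = n_bact),
      list(type = "bacterium", state = "tolerogenic", count = n_bact),
      list(type = "t_cell", state = "naive", count = n_tcell),
      list(type = "dendritic_cell", state = "immature", count = n_dc)),
    cycles = cycles, seed = seed, ...)
}

file_md5 <- function(path) unname(tools::md5sum(path))
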