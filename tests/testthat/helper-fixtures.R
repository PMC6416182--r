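# fixture builders shared across the suite; everything is generated in code

cylinder_cloud <- function(n = 1500, radius = 0.01, length = 1, seed = 1) {
  withr::with_seed(seed, {
    z <- runif(n, 0, length)
    th <- runif(n, 0, 2 * pi)
    cbind(radius * cos(th), radius * sin(th), z)
  })
}

# three straight segments meeting at the origin (a Y junction)
y_junction <- function(n_per = 200, jitter = 0, seed = 1) {
  dirs <- rbind(c(0, 0, 1), c(0.8, 0, -0.6), c(-0.8, 0, -0.6))
  withr::with_seed(seed, {
    P <- do.call(rbind, lapply(1:3, function(i)
      outer(seq(0.002, 0.5, length.out = n_per), dirs[i, ])))
    if (jitter > 0) P <- P + matrix(rnorm(length(P), 0, jitter), ncol = 3)
    P
  })
}

const_color <- function(n, rgb = c(40, 150, 40)) {
  matrix(rep(rgb, each = n), n)
}

grid_cloud <- function(k = 4, spacing = 1) {
  g <- expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1)) * spacing
  point_cloud(as.matrix(g), const_color(k^3))
}

small_plant <- function(seed = 5, points = 6000, noise = 0.001,
                        pot = FALSE, outliers = 0) {
  make_plant(plant_spec(seed = seed, height = 1.5, noise_sigma = noise,
                        points_per_plant = points, pot = pot,
                        outlier_fraction = outliers))
}
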