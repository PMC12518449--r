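# Shared fixtures, built in code: the workbench default grid and a few
# frequently used landscapes.

grid_default <- function() trait_grid(80, 1600)

# single quadratic peak (5/2 - (x - 40)^2)^+ - 1/2, speed 1
peak1 <- function() preset_landscape("peak1")

# flat fitness g on a wide plateau (logistic-oracle landscape)
flat_landscape <- function(g = 1.5, d = 0.5, lo = 8, hi = 72) {
  custom_landscape(function(x) (g + d) * (x > lo & x < hi), d = d,
                   support_lo = lo, support_hi = hi, epsilon = 0.1)
}

logistic_mass <- function(t, r0, g) g * r0 * exp(g * t) /
  (g + r0 * (exp(g * t) - 1))

# caption phase initial conditions (fig5)
u0_fig5 <- function(epsilon) {
  function(x) -epsilon * (log(1 / 10) - (x - 37.5)^2 / 10^2)
}
v0_fig5 <- function() function(x) 0.1 * (x - 37.5)^2 / 100
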