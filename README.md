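# fsmotion

Validation tools for the **Fujimura–Sugihara (FS) sprint motion model** on
player tracking data, for sports scientists and match analysts who use
physics-based motion models in space evaluation, pass prediction and
dominant-region analysis.

A player sprinting under a constant driving force with viscous resistance
obeys

$$ m\,\ddot{\vec x}(t) = F\,\hat n - k\,\dot{\vec x}(t), $$

whose solution from initial velocity $\vec v_0$ is

$$ \vec x(t) = A(\alpha, t)\,\vec v_0 + B(\alpha, V_{\max}, t)\,\hat n,
   \qquad A = \frac{1 - e^{-\alpha t}}{\alpha}, \qquad
   B = V_{\max}(t - A), $$

with kinetic parameters $\alpha = k/m$ (drag-to-mass ratio, 1/s) and
$V_{\max} = F/k$ (terminal sprint speed, m/s). Sweeping the driving
direction, the positions reachable in $\Delta t$ seconds lie on the
**arrival circle** with centre $A\vec v_0$ and radius $B$. The package

* implements the closed form, arrival-circle geometry and a fixed-step RK4
  integrator for the time-varying-coefficient extension
  $m\ddot{\vec x} = F(t)\hat n(t) - k(t)\dot{\vec x}$;
* builds **velocity-frame heat maps** of arrival points from tracking data
  (0.3 m/s initial-speed bins, $0.2\,\Delta t$ m cells, Moore-neighbour
  isolated-cell filtering) and estimates each map's boundary circle from
  its extents;
* inverts the circle geometry into the kinetic parameters: the
  centre-vs-speed slope gives $\alpha$ (bracketed root of
  $A(\alpha, \Delta t) = \text{slope}$), the pooled mean radius gives
  $V_{\max}$; `sweep_delta_t()` repeats this across intervals;
* analyses trajectory kinematics: 1 s lagged velocities, speed
  distributions, and mean-squared-displacement scaling
  ($\beta = 2$ ballistic → $\beta = 1$ diffusive crossover);
* generates **seeded synthetic tracking data** (walk/jog/sprint Markov
  states on exact FS dynamics, ~10 s straight runs, ±1 m optical-tracking
  noise) so the whole pipeline runs without proprietary match data.

Everything is tidyverse-native: tracking data and results are tibbles,
fitted objects have `tidy()`/`glance()` methods, and heat maps and fits
have `autoplot()` methods.

## Worked example

Arrival circle of a player moving at 4 m/s with the classic sprint
parameters $\alpha = 1.3$ 1/s, $V_{\max} = 7.8$ m/s:

```r
library(fsmotion)
p <- kinetic_params(alpha = 1.3, vmax = 7.8)
arrival_circle(c(4, 0), p, t = 2)
#> # A tibble: 1 × 4
#>   center_x center_y radius delta_t
#>      <dbl>    <dbl>  <dbl>   <dbl>
#> 1     2.85        0   10.0       2
```

After 2 s the reachable boundary is a circle of radius 10.0 m whose centre
has drifted 2.85 m along the initial velocity — the decaying memory of
$\vec v_0$.

Published heat-map measurements invert directly: a centre-vs-speed slope
of 0.58 at $\Delta t = 1$ s and a mean circle radius of 6.16 m give

```r
invert_alpha(0.58, 1)            # 1.21001  (1/s)
vmax_from_radius(6.16, 1.23, 1)  # 14.50681 (m/s)
```

End to end on synthetic sprint ensembles (720 directions per 0.3 m/s bin,
±1 m tracking noise, generated from the model with $\alpha = 1.04$,
$V_{\max} = 11.19$ at $\Delta t = 2$ s):

```r
est <- purrr::map_dfr(seq(0, 6, 0.3), function(lo) {
  ens <- generate_sprint_ensemble(kinetic_params(1.04, 11.19), v0 = lo + 0.15,
                                  delta_t = 2, n_directions = 720,
                                  noise_sigma = 0.5, seed = 1000 + lo * 10)
  g <- filter_isolated_cells(build_heatmap(ens, 2, c(lo, lo + 0.3)), 6)
  circle_from_extent(g)
})
estimate_params(est, delta_t = 2)
#> <kinetic_fit> delta_t = 2 s (21 bins, v0 <= 6 m/s)
#>   slope A  = 0.8274 s
#>   alpha    = 1.0650 1/s
#>   mean r_c = 13.0000 m
#>   vmax     = 11.0863 m/s
```

The heat-map chain recovers the generating parameters to a few percent.
For a full synthetic match, `run_validation(pipeline_config())` chains
generation → speed distribution → MSD exponents → heat maps → circle
estimates → kinetic fits and can write every table as CSV; see the
vignette (`vignettes/sprint-arrival-model.Rmd`) for the model, the
estimator's noise sensitivity at small $\Delta t$, and the generator
design.

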