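# patchpath

Non-planar lattice toolpaths for robot-arm biomaterial deposition on curved
anatomical surfaces, with a kinematic benchmark that picks the waypoint
spacing the hardware cannot distinguish from ideal.

Printing a scaffold *onto* a curved surface patch (for example a ~20 mm
region of a humeral head) defeats conventional planar slicers. `patchpath`
instead slices the triangulated patch (STL, mm units) with two orthogonal
families of parallel vertical planes spaced `d` apart; each plane–surface
intersection is a curve on the surface, and the curves are serpentine-
ordered, resampled to a maximum waypoint spacing `S`, and joined by
shortest-vector travel moves into one connected lattice path whose pores
have pitch `d`. A 4-DOF arm model (base yaw + parallelogram shoulder/elbow
keeping the tool vertical + wrist yaw, analytic forward/inverse kinematics)
then executes a circular reference trajectory of diameter `D` discretized
into `N` waypoints, with arc step

    S = pi * D / N,

and reports the mean and standard deviation of the sampled radial distance
from the centre. The coarsest `N` whose deviation falls below the arm's
repeatability `eps` (0.05 mm for MG400-class arms) fixes `S` for path
resampling; on the 20 mm circle that is `N = 30`, `S = 2.09 mm`, deviation
~0.02 mm.

## Worked example

```r
library(patchpath)

# synthetic patch: spherical cap, 20 mm footprint on a 25 mm sphere
cap  <- make_spherical_cap(cap_diameter = 20, sphere_radius = 25,
                           resolution = 0.5)
path <- generate_lattice_path(cap, d = 1, max_step = 2.09)
path_metrics(path)
#> # A tibble: 1 x 7
#>   total_deposit_mm total_travel_mm n_points max_deposit_spacing_mm n_x_lines n_y_lines pore_pitch_mm
#>              <dbl>           <dbl>    <int>                  <dbl>     <int>     <int>         <dbl>
#> 1             635.            63.7     3926                  0.639        19        19          1.00
```

635 mm of filament in 19 + 19 conformal lines at 1 mm pore pitch, every
deposit point on the cap surface to within 1e-6 mm (`autoplot(path)` draws
the lattice). The discretization study behind the 2.09 mm default:

```r
rep <- discretization_report(arm_model(), N_list = c(5, 10, 20, 30), D = 20)
rep
#>       N  S_mm mean_radius std_radius rms_dev n_samples below_threshold
#>   <int> <dbl>       <dbl>      <dbl>   <dbl>     <int> <lgl>
#> 1     5 12.6         8.75     0.578   1.37        1000 FALSE
#> 2    10  6.28        9.68     0.146   0.356       2000 FALSE
#> 3    20  3.14        9.92     0.0367  0.0898      4000 TRUE
#> 4    30  2.09        9.96     0.0163  0.0400      6000 TRUE
```

Reading the table: at `N = 5` the inscribed polygon is 1.25 mm short of the
ideal 10 mm radius on average and scatters by 0.58 mm; by `N = 30` the
deviation (0.016 mm, printed 0.02) is inside the arm's 0.05 mm
repeatability band (`below_threshold`), so finer discretization buys
nothing the hardware can express. `autoplot(rep)` plots the deviation
against the shaded repeatability band; `tidy()`/`glance()` extract
per-sample and summary tables from `run_circle_benchmark()` objects.

A command-line front end wraps the same functions
(`exec/patchpath`, installed to the package's `exec/` directory):

```sh
patchpath fixture   --kind spherical_cap --diameter 20 --sphere-radius 25 -o cap.stl
patchpath lattice   -i cap.stl -d 1 --max-step 2.09 -o path.csv
patchpath benchmark --n 5,10,20,30 --eps 0.05 -o table.csv
patchpath pipeline  -o rundir          # fixture -> slice -> lattice -> benchmark
```

See `vignettes/conformal-toolpaths.Rmd` for the geometric conventions
(plane placement, tangential-contact policy, tolerances), the arm model
and the reasoning behind the statistic definitions.

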