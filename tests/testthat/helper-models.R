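# Shared small models, built once per test run and cached.

.models <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.models[[name]])) .models[[name]] <- force(expr)
  .models[[name]]
}

# degenerate closed spherical shell: cavity radius 9 mm, wall 0.5 mm
tiny_sphere_mesh <- function() {
  cached("sphere_mesh", {
    p <- globe_params(AL = 19, EL = 19, THK = 0.5, t_post = 0.5,
                      t_cornea = 0.5, apex_offset = 0)
    generate_mesh(p, resolution = 250)
  })
}

tiny_sphere_inflation <- function() {
  cached("sphere_sol", {
    m <- tiny_sphere_mesh()
    f <- material_field(m, mu = 0.083, mu_post = 0.083, mu_cornea = 0.083)
    b <- boundary_conditions(m)
    pr_mmhg <- 2 / 133.322e-3   # 2 kPa
    sol <- solve_static(m, f, b, data.frame(iop_mmhg = pr_mmhg, puff_frac = 0))
    list(mesh = m, field = f, bcs = b, sol = sol, p_mpa = 0.002)
  })
}

# coarse baseline globe, full forward run (shared by preload/airpuff/metrics)
tiny_globe_forward <- function() {
  cached("globe_fwd", run_forward(resolution = 150))
}

test_resolution <- function() 150
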