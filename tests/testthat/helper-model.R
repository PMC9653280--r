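# Shared fixtures: models are expensive, so heavyweight objects are built
# once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_section <- function() fixture("section", build_section(8.5))

default_model <- function() fixture("model", build_model(8.5, span_mm = 0.2))

default_eff <- function() {
  fixture("eff", {
    m <- default_model()
    effective_system(m$system, m$coupling)
  })
}

default_field_1khz <- function() {
  fixture("field1k", solve_frequency(default_model()$system, default_eff(), 1000))
}

small_system <- function() {
  fixture("smallsys", assemble_structure(default_section(), nsec = 5))
}

# small planar fluid problem on a 2 mm chamber for oracle-sized tests
small_coupling <- function() {
  fixture("smallcpl", {
    sys <- small_system()
    sec <- default_section()
    ifc <- sys$interface
    mesh <- build_fluid_mesh(chamber_width = 2, channel_height = 0.5,
                             slit_span = sec$bm_width_um * 1e-3,
                             slit_center = 1, refinement = 4,
                             bottom_faces = c(ifc$bottom$x0, tail(ifc$bottom$x1, 1)),
                             top_faces = c(ifc$top$x0, tail(ifc$top$x1, 1)))
    assemble_coupling(mesh, ifc, depth = 0.01)
  })
}

rtm_sweep <- function() {
  fixture("rtm_sweep",
          sweep_ratio("rtm", grid = log_grid(0.1, 10, 9), freq_hz = 1000))
}

rdc_sweep <- function() {
  fixture("rdc_sweep",
          sweep_ratio("rdc", grid = log_grid(0.1, 10, 9), freq_hz = 1000))
}

freq_response_15 <- function() {
  fixture("freq15", {
    # dynamic comparisons use the model after its static volume compliance
    # has been matched to the measured value, as in the study design
    cal <- calibrated_model()
    eff <- effective_system(cal$model$system, cal$model$coupling)
    frequency_sweep(cal$model$system, eff, log_grid(300, 5000, 15))
  })
}

calibrated_model <- function() {
  fixture("calibrated", calibrate_bm_modulus(8.5, target_mm4_per_n = 16.1))
}
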