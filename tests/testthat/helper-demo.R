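# The seeded end-to-end phantom study is trained once per test session and
# shared by the acceptance tests that probe it.
.demo_env <- new.env(parent = emptyenv())

get_demo_run <- function() {
  if (is.null(.demo_env$run)) .demo_env$run <- run_phantom_demo(seed = 1L)
  .demo_env$run
}

n_components_26 <- function(mask) {
  dm <- dim(mask)
  max(e2dseg:::cpp_label3d(as.integer(mask), dm[1], dm[2], dm[3]))
}
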