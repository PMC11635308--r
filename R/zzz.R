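.onLoad <- function(libname, pkgname) {
  register_tpc_form("beta", tpc_shape_beta)
  # sharpened variant for sensitivity checks: same cardinal temperatures and
  # argmax, narrower shoulders
  register_tpc_form("beta2", function(temp, t_min, t_opt, t_max) {
    tpc_shape_beta(temp, t_min, t_opt, t_max)^2
  })
}
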