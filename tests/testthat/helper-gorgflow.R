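# Shared helpers: a scaled-down unit cell (same structure as the real ones,
# shorter domain and cylinder) so solver-backed property tests run in
# seconds, plus a solve wrapper that silences regime/plateau warnings.

mini_cell <- function(g_over_d = 1, height = 0.2, length = 1.6,
                      domain_height = 0.6, offset = 0.5) {
  gorgflow:::new_cylinder_cell("branch", diameter = 0.1, height = height,
                               g_over_d = g_over_d,
                               domain_length = length,
                               domain_height = domain_height,
                               inlet_offset = offset)
}

quiet_solve <- function(cell, U, ...) {
  suppressWarnings(solve_steady(cell, U, ...))
}

fast_settings <- function(...) {
  args <- modifyList(list(max_iter = 30000L, check_every = 100L), list(...))
  do.call(solver_settings, args)
}

# cache one mini-cell solution per test file run
mini_field <- local({
  cache <- new.env(parent = emptyenv())
  function(g_over_d = 1, U = 0.5) {
    key <- sprintf("%g|%g", g_over_d, U)
    if (is.null(cache[[key]])) {
      cache[[key]] <- quiet_solve(mini_cell(g_over_d), U,
                                  settings = fast_settings())
    }
    cache[[key]]
  }
})
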