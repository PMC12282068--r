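# Lazily computed, shared toy objects so the expensive dFBA runs happen
# at most once per test session.

.toy_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .toy_cache)) {
    assign(name, force(expr), .toy_cache)
  }
  get(name, .toy_cache)
}

toy_fixture <- function() cached("toy", make_toy_ccm())

toy_traj <- function(kind = "morp") {
  cached(paste0("traj_", kind), {
    sc <- toy_scenario(objective_kind = kind)
    simulate_dfba(sc$model, sc$schedule, sc$kinetics, sc$species,
                  sc$init, t_end = sc$t_end, dt = sc$dt)
  })
}

# window of a phase: first and last state times carrying that label
phase_window <- function(traj, ph) {
  idx <- which(traj$phase_labels == ph)
  c(traj$states$t[idx[1]], traj$states$t[idx[length(idx)] + 1])
}
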