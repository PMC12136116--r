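# Shared, lazily built fixtures: the default head model / montage /
# prediction matrix, and a reduced-scale simulated study (6 participants,
# 2 repetitions per condition). Built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fix_head <- function() fixture("head", head_model)
fix_montage <- function() fixture("montage", function() default_montage(128))
fix_predictions <- function() fixture("pm", function()
  build_prediction_matrix(retinotopic_patches(fix_head()), fix_head(),
                          fix_montage()))

# small montage / two-area predictions for cheap unit tests
fix_small <- function() fixture("small", function() {
  mon <- default_montage(16)
  sig <- default_area_signatures()[1:2, ]
  pm <- suppressWarnings(build_prediction_matrix(
    retinotopic_patches(fix_head(), n_wedges = 4, signatures = sig),
    fix_head(), mon))
  list(montage = mon, pm = pm)
})

# reduced-scale study pieces shared by the end-to-end tests
fix_reduced <- function() fixture("reduced", function() {
  cfg <- simulation_config(n_participants = 6, n_repetitions = 2, seed = 11)
  tr <- design_pulse_train(n_repetitions = 2, seed = 11)
  ep <- epoch_grid(fs = cfg$fs)
  imp <- resample_events(tr, cfg$fs)
  pm <- fix_predictions()
  mon <- fix_montage()
  kern <- list(pulse = make_source_kernels("pulse", ep, cfg),
               reversal = make_source_kernels("reversal", ep, cfg))
  comps <- lapply(kern, function(k)
    signal_components(cfg, tr, pm, k, ep))
  des <- deconv_design(imp, ep, comps$pulse$blocks)
  list(cfg = cfg, train = tr, epoch = ep, imp = imp, pm = pm, mon = mon,
       kernels = kern, comps = comps, design = des)
})

# grand-average deconvolved estimate for one condition and seed offset
reduced_grand <- function(condition, seed_base, n_participants = 6) {
  rd <- fix_reduced()
  ests <- lapply(seq_len(n_participants), function(p) {
    sim <- simulate_participant(rd$cfg, rd$train, rd$pm,
                                rd$kernels[[condition]], rd$epoch, rd$mon,
                                seed_base + p, rd$comps[[condition]])
    estimate_mvep(sim$recording, rd$imp, rd$epoch, design = rd$design,
                  condition = condition, participant = paste0("p", p))
  })
  grand_average(ests)
}

# the default reduced-scale grand averages (one realization per condition)
fix_grand <- function() fixture("grand", function()
  list(pulse = reduced_grand("pulse", 5000),
       reversal = reduced_grand("reversal", 6000)))
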