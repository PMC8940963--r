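# Shared small fixtures, generated once per test run.

fix_cfg <- synth_config(n_units = 15, n_trials_per_type = 8,
                        dprime_target_distribution = c(1.2, 0.4),
                        seed = 101)
fix_sess <- generate_session(fix_cfg)
fix_epochs_br <- segment_session(fix_sess, "BR")
fix_epochs_pa <- epochs_from_events(fix_sess, "PA")

# one flat-rate alignment set reused by PSTH tests
fix_switches_br <- epoch_switches(fix_epochs_br)
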