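# Shared study-condition fixtures: a CCB-like model, the packaged Co-60
# correction table and a diode-like calibration coefficient.
syn_model <- function(...) synthetic_model(...)

syn_cal <- function(quality = "Co60", value = 0.05)
  calibration_coefficient(quality, value, u_rel = 0.5)

syn_kq <- function(quality = "Co60") ccb_kq_table(quality)

# A quick zero-noise session/curve pair under the default conditions.
syn_session <- function(model = syn_model(), noise_rel = 0, seed = 1, ...)
  simulate_session(model, calibration = syn_cal(), kq = syn_kq(),
                   noise_rel = noise_rel, background_rate = 1e-4,
                   seed = seed, ...)

as_ts <- function(x) as.POSIXct(x, tz = "UTC")
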