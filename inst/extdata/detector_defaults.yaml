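# Default HFA detector parameters. All detectors band-pass 80-500 Hz first
# (upper edge clipped below Nyquist at detection time). Values follow the
# original detector publications: short-time energy (Staba 2002), short
# line length (Gardner 2007), Hilbert envelope (Crepon 2010), and the
# Montreal Neurological Institute baseline method (Zelmann 2012).
ste:
  band: [80, 500]
  filter_order: 128
  rms_window_ms: 3        # moving RMS window
  threshold_sd: 5         # primary: RMS > mean + k*SD
  min_duration_ms: 6
  peak_threshold_sd: 3    # secondary: rectified peaks above mean + k*SD
  min_peaks: 6
  peak_context_ms: 20     # context window for the peak count
  merge_gap_ms: 10
sll:
  band: [80, 500]
  filter_order: 128
  window_ms: 40           # moving line-length window
  percentile: 97.5        # primary: empirical percentile threshold
  min_duration_ms: 12
  merge_gap_ms: 10
hil:
  band: [80, 500]
  filter_order: 128
  threshold_sd: 5         # primary: Hilbert envelope > mean + k*SD
  epoch_s: 10             # sliding threshold-estimation epoch
  min_duration_ms: 10
  merge_gap_ms: 10
mni:
  band: [80, 500]
  filter_order: 128
  energy_window_ms: 10    # moving energy window
  baseline_window_ms: 125 # candidate baseline segment length
  baseline_sd: 2          # segment is baseline if peak rectified amplitude
                          # stays below mean + k*SD
  min_baseline_s: 5       # fall back to iterative scheme below this
  baseline_percentile: 99.99   # primary: gamma-CDF threshold on baseline energy
  fallback_percentile: 99.95   # iterative empirical percentile fallback
  min_duration_ms: 10
  merge_gap_ms: 10
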