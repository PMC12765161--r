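# Column-name mapping for the four deposited long-call datasets.
#
# The deposit's exact column headers are not fixed by this package; edit the
# right-hand sides below to match the headers found in the downloaded files,
# then pass the parsed mapping to read_events(..., mapping = yaml::read_yaml(...)).
# Left-hand sides are the pipeline's canonical field names. `file` is the
# expected file name inside the deposit directory (used by reproduce_paper()).

zenodo_tempo:
  file: tempo_analyses.csv
  columns:
    file_id: file_id
    section_id: section_id
    tk_type: tk_type        # series | pants | pulses
    t_k: t_k

zenodo_granger:
  file: granger_starting_points.csv
  columns:
    file_id: file_id
    call_id: call_id
    section_id: section_id
    kind: kind              # pulse | pant
    onset_s: onset_s
    duration_s: duration_s

zenodo_tk_rk:
  file: tk_rk_pulses_pants.csv
  columns:
    file_id: file_id
    section_id: section_id
    kind: kind              # which element type the interval series came from
    t_k: t_k
    r_k: r_k

zenodo_rk_overall:
  file: rk_pulses_overall.csv
  columns:
    file_id: file_id
    call_id: call_id
    t_k: t_k
    r_k: r_k
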