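# Packaged fixture tables

Values transcribed from the published summary tables of the motivating field
campaign: a 19-sensor low-cost PM2.5 network deployed across 15 sites in six
Sacramento communities during winter 2016/17, with pre- and post-study
collocation at a regulatory monitoring site.

- `collocation_precision.csv` — per-sensor collocation statistics: hours of
  valid data, R² and RMSE versus the 19-sensor hourly mean, regression slope
  and intercept for the pre- and post-study collocation periods, and the
  averaged correction-factor columns. `cf_source` marks rows whose printed
  correction factor equals the pre-study coefficients rather than the
  pre/post average (post-study data were invalid for those sensors).
- `site_distances_km.csv` — lower-triangular matrix of great-circle distances
  (km) between the 15 community sites, grouped by community.
- `pairwise_r2.csv` — pairwise Pearson R² between site series; lower triangle
  from hourly values, upper triangle from daily averages.
- `pairwise_cod.csv` — pairwise coefficient of divergence; lower triangle
  hourly, upper triangle daily.

All files are plain CSV with site and community label columns. Matrix files
share one site ordering.
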