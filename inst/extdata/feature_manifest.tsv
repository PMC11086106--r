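name	family	input
mean	time-moments	mean-signal
variance	time-moments	mean-signal
std	time-moments	mean-signal
skewness	time-moments	mean-signal
kurtosis	time-moments	mean-signal
activity	hjorth	mean-signal
mobility	hjorth	mean-signal
complexity	hjorth	mean-signal
spectral_entropy	spectral-entropy	mean-signal
abs_power_delta	abs-band-power	mean-signal
abs_power_theta	abs-band-power	mean-signal
abs_power_alpha	abs-band-power	mean-signal
abs_power_beta	abs-band-power	mean-signal
abs_power_gamma	abs-band-power	mean-signal
rel_power_delta	rel-band-power	mean-signal
rel_power_theta	rel-band-power	mean-signal
rel_power_alpha	rel-band-power	mean-signal
rel_power_beta	rel-band-power	mean-signal
rel_power_gamma	rel-band-power	mean-signal
ratio_theta_alpha	band-ratio	mean-signal
ratio_beta_slow	band-ratio	mean-signal
left_logpower_delta	hemi-band-power	hemisphere-means
left_logpower_theta	hemi-band-power	hemisphere-means
left_logpower_alpha	hemi-band-power	hemisphere-means
left_logpower_beta	hemi-band-power	hemisphere-means
left_logpower_gamma	hemi-band-power	hemisphere-means
right_logpower_delta	hemi-band-power	hemisphere-means
right_logpower_theta	hemi-band-power	hemisphere-means
right_logpower_alpha	hemi-band-power	hemisphere-means
right_logpower_beta	hemi-band-power	hemisphere-means
right_logpower_gamma	hemi-band-power	hemisphere-means
asym_delta	hemi-asymmetry	hemisphere-means
asym_theta	hemi-asymmetry	hemisphere-means
asym_alpha	hemi-asymmetry	hemisphere-means
asym_beta	hemi-asymmetry	hemisphere-means
asym_gamma	hemi-asymmetry	hemisphere-means
line_length	shape	mean-signal
zero_cross_rate	shape	mean-signal
rms	shape	mean-signal
iqr	shape	mean-signal
diff_line_length	shape-diff	first-difference
diff_zero_cross_rate	shape-diff	first-difference
diff_rms	shape-diff	first-difference
diff_iqr	shape-diff	first-difference
diff_mean	time-moments-diff	first-difference
diff_variance	time-moments-diff	first-difference
diff_std	time-moments-diff	first-difference
diff_skewness	time-moments-diff	first-difference
diff_kurtosis	time-moments-diff	first-difference
diff_activity	hjorth-diff	first-difference
diff_mobility	hjorth-diff	first-difference
diff_complexity	hjorth-diff	first-difference
diff_spectral_entropy	spectral-entropy-diff	first-difference
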