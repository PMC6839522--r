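Place the published supplementary data matrix (NEXUS or TNT format,
114 taxa x 202 characters) here as `matrix.nex` before installing, or set
options(maxpars.study_matrix = "/path/to/matrix.nex") at run time.
The file is third-party supplementary material and is not redistributed
with this package; without it the study-reproduction acceptance tests
fail with an explanatory message. See ?study_matrix_path.
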