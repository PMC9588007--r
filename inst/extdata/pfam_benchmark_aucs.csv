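family,method,cutoff,auc_eq,auc_tree,delta_printed
PF00004,plmdca,N,0.87,0.58,0.33
PF00005,plmdca,N,0.93,0.67,0.28
PF00041,plmdca,N,0.86,0.64,0.25
PF00072,plmdca,N,0.94,0.73,0.23
PF00076,plmdca,N,0.92,0.69,0.25
PF00096,plmdca,N,0.88,0.54,0.39
PF00153,plmdca,N,0.95,0.71,0.26
PF00271,plmdca,N,0.91,0.62,0.32
PF00397,plmdca,N,0.85,0.58,0.33
PF00512,plmdca,N,0.94,0.74,0.21
PF00595,plmdca,N,0.91,0.61,0.33
PF01535,plmdca,N,0.85,0.66,0.23
PF02518,plmdca,N,0.93,0.69,0.27
PF07679,plmdca,N,0.85,0.63,0.26
PF13354,plmdca,N,0.68,0.56,0.18
PF00004,msa_transformer,N,0.70,0.67,0.04
PF00005,msa_transformer,N,0.79,0.76,0.03
PF00041,msa_transformer,N,0.69,0.62,0.10
PF00072,msa_transformer,N,0.86,0.77,0.10
PF00076,msa_transformer,N,0.81,0.76,0.05
PF00096,msa_transformer,N,0.68,0.54,0.21
PF00153,msa_transformer,N,0.83,0.63,0.24
PF00271,msa_transformer,N,0.78,0.72,0.07
PF00397,msa_transformer,N,0.69,0.58,0.15
PF00512,msa_transformer,N,0.84,0.77,0.08
PF00595,msa_transformer,N,0.72,0.62,0.14
PF01535,msa_transformer,N,0.66,0.63,0.05
PF02518,msa_transformer,N,0.82,0.75,0.09
PF07679,msa_transformer,N,0.68,0.64,0.05
PF13354,msa_transformer,N,0.76,0.65,0.14
PF00004,plmdca,2L,0.93,0.61,0.34
PF00005,plmdca,2L,0.96,0.74,0.23
PF00041,plmdca,2L,0.94,0.73,0.22
PF00072,plmdca,2L,0.99,0.85,0.14
PF00076,plmdca,2L,0.97,0.72,0.25
PF00096,plmdca,2L,0.92,0.54,0.41
PF00153,plmdca,2L,0.98,0.77,0.21
PF00271,plmdca,2L,0.95,0.67,0.29
PF00397,plmdca,2L,0.93,0.61,0.34
PF00512,plmdca,2L,0.97,0.78,0.20
PF00595,plmdca,2L,0.96,0.64,0.33
PF01535,plmdca,2L,0.88,0.72,0.18
PF02518,plmdca,2L,0.98,0.78,0.20
PF07679,plmdca,2L,0.95,0.77,0.19
PF13354,plmdca,2L,0.82,0.65,0.21
PF00004,msa_transformer,2L,0.80,0.71,0.11
PF00005,msa_transformer,2L,0.81,0.82,-0.01
PF00041,msa_transformer,2L,0.87,0.79,0.09
PF00072,msa_transformer,2L,0.94,0.87,0.08
PF00076,msa_transformer,2L,0.88,0.83,0.05
PF00096,msa_transformer,2L,0.78,0.54,0.30
PF00153,msa_transformer,2L,0.90,0.65,0.28
PF00271,msa_transformer,2L,0.85,0.77,0.10
PF00397,msa_transformer,2L,0.76,0.59,0.22
PF00512,msa_transformer,2L,0.88,0.81,0.08
PF00595,msa_transformer,2L,0.83,0.68,0.18
PF01535,msa_transformer,2L,0.73,0.72,0.01
PF02518,msa_transformer,2L,0.90,0.79,0.12
PF07679,msa_transformer,2L,0.85,0.80,0.05
PF13354,msa_transformer,2L,0.91,0.74,0.19
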