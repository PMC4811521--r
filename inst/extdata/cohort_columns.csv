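"column","type","meaning"
"patient_id","character","unique patient identifier"
"os_months","numeric > 0","overall survival in months after CRCLM resection"
"event","0/1","1 = died, 0 = censored"
"interval_lt_12mo","0/1","primary tumor-to-CRCLM interval < 12 months"
"node_positive","0/1","lymph-node positive primary tumor"
"diameter_gt_5cm","0/1","maximal CRCLM diameter > 5.0 cm"
"multiple_crclm","0/1","number of CRCLM > 1"
"cea_gt_200","0/1","serum CEA > 200 ng/ml"
"systemic_therapy","0/1 or empty","systemic therapy for the CRCLM"
"primary_site","colon/rectum or empty","location of the primary tumor"
"EGFR_crclm_int","integer 0-3 or empty","EGFR intensity score, liver metastasis"
"EGFR_prim_int","integer 0-3 or empty","EGFR intensity score, primary tumor"
"EGFR_crclm_freq","integer 0-3 or empty","EGFR frequency score, liver metastasis"
"EGFR_prim_freq","integer 0-3 or empty","EGFR frequency score, primary tumor"
"AURKA_crclm_int","integer 0-3 or empty","AURKA intensity score, liver metastasis"
"AURKA_prim_int","integer 0-3 or empty","AURKA intensity score, primary tumor"
"AURKA_crclm_freq","integer 0-3 or empty","AURKA frequency score, liver metastasis"
"AURKA_prim_freq","integer 0-3 or empty","AURKA frequency score, primary tumor"
"VEGFA_crclm_int","integer 0-3 or empty","VEGFA intensity score, liver metastasis"
"VEGFA_prim_int","integer 0-3 or empty","VEGFA intensity score, primary tumor"
"VEGFA_crclm_freq","integer 0-3 or empty","VEGFA frequency score, liver metastasis"
"VEGFA_prim_freq","integer 0-3 or empty","VEGFA frequency score, primary tumor"
"PTGS2_crclm_int","integer 0-3 or empty","PTGS2 intensity score, liver metastasis"
"PTGS2_prim_int","integer 0-3 or empty","PTGS2 intensity score, primary tumor"
"PTGS2_crclm_freq","integer 0-3 or empty","PTGS2 frequency score, liver metastasis"
"PTGS2_prim_freq","integer 0-3 or empty","PTGS2 frequency score, primary tumor"
"SLC2A1_crclm_int","integer 0-3 or empty","SLC2A1 intensity score, liver metastasis"
"SLC2A1_prim_int","integer 0-3 or empty","SLC2A1 intensity score, primary tumor"
"SLC2A1_crclm_freq","integer 0-3 or empty","SLC2A1 frequency score, liver metastasis"
"SLC2A1_prim_freq","integer 0-3 or empty","SLC2A1 frequency score, primary tumor"
"HIF1A_crclm_int","integer 0-3 or empty","HIF1A intensity score, liver metastasis"
"HIF1A_prim_int","integer 0-3 or empty","HIF1A intensity score, primary tumor"
"HIF1A_crclm_freq","integer 0-3 or empty","HIF1A frequency score, liver metastasis"
"HIF1A_prim_freq","integer 0-3 or empty","HIF1A frequency score, primary tumor"
"KCNQ1_crclm_int","integer 0-3 or empty","KCNQ1 intensity score, liver metastasis"
"KCNQ1_prim_int","integer 0-3 or empty","KCNQ1 intensity score, primary tumor"
"KCNQ1_crclm_freq","integer 0-3 or empty","KCNQ1 frequency score, liver metastasis"
"KCNQ1_prim_freq","integer 0-3 or empty","KCNQ1 frequency score, primary tumor"
"CEA_crclm_int","integer 0-3 or empty","CEA intensity score, liver metastasis"
"CEA_prim_int","integer 0-3 or empty","CEA intensity score, primary tumor"
"CEA_crclm_freq","integer 0-3 or empty","CEA frequency score, liver metastasis"
"CEA_prim_freq","integer 0-3 or empty","CEA frequency score, primary tumor"
"MMP9_crclm_int","integer 0-3 or empty","MMP9 intensity score, liver metastasis"
"MMP9_prim_int","integer 0-3 or empty","MMP9 intensity score, primary tumor"
"MMP9_crclm_freq","integer 0-3 or empty","MMP9 frequency score, liver metastasis"
"MMP9_prim_freq","integer 0-3 or empty","MMP9 frequency score, primary tumor"
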