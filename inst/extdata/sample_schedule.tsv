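patient_id	timepoint	collected
UMB-009	baseline	yes
UMB-009	2wk	yes
UMB-009	3mo	yes
UMB-009	6mo	yes
UMB-009	12mo	no
UMB-003	baseline	yes
UMB-003	2wk	yes
UMB-003	3mo	yes
UMB-003	6mo	yes
UMB-003	12mo	no
UMB-005	baseline	yes
UMB-005	2wk	yes
UMB-005	3mo	yes
UMB-005	6mo	yes
UMB-005	12mo	no
UMB-004	baseline	no
UMB-004	2wk	yes
UMB-004	3mo	yes
UMB-004	6mo	yes
UMB-004	12mo	yes
UMB-006	baseline	yes
UMB-006	2wk	yes
UMB-006	3mo	yes
UMB-006	6mo	yes
UMB-006	12mo	yes
UMB-001	baseline	yes
UMB-001	2wk	yes
UMB-001	3mo	yes
UMB-001	6mo	yes
UMB-001	12mo	yes
UMB-002	baseline	yes
UMB-002	2wk	yes
UMB-002	3mo	yes
UMB-002	6mo	yes
UMB-002	12mo	yes
UMB-011	baseline	yes
UMB-011	2wk	yes
UMB-011	3mo	yes
UMB-011	6mo	yes
UMB-011	12mo	yes
UMB-007	baseline	yes
UMB-007	2wk	yes
UMB-007	3mo	yes
UMB-007	6mo	yes
UMB-007	12mo	no
UMB-008	baseline	yes
UMB-008	2wk	no
UMB-008	3mo	no
UMB-008	6mo	no
UMB-008	12mo	no
UMB-010	baseline	yes
UMB-010	2wk	yes
UMB-010	3mo	yes
UMB-010	6mo	yes
UMB-010	12mo	yes
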