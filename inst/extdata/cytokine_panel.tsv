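analyte	alias
CCL1	I-309
CCL2	MCP-1
CCL3	MIP-1alpha
CCL7	MCP-3
CCL8	MCP-2
CCL11	EOTAXIN
CCL13	MCP-4
CCL15	MIP-1delta
CCL19	MIP-3beta
CCL20	MIP-3alpha
CCL21	6Ckine
CCL22	MDC
CCL23	MPIF-1
CCL24	EOTAXIN-2
CCL25	TECK
CCL26	EOTAXIN-3
CX3CL1	Fractalkine
CXCL1	Gro-alpha
CXCL2	Gro-beta
CXCL6	GCP-2
CXCL8	IL-8
CXCL9	MIG
CXCL10	IP-10
CXCL11	I-TAC
CXCL12	SDF-1
CXCL13	BCA-1
CXCL16	SCYB16
FGF-basic	FGF2
IFN-gamma	IFN-gamma
IL-10	IL-10
IL-16	IL-16
IL-2	IL-2
MIF	MIF
TNF-alpha	TNF-alpha
ANG-1	Angiopoietin-1
ANG-2	Angiopoietin-2
IL-1alpha	IL-1alpha
SCF	SCF
VEGF	VEGF
IL-1beta	IL-1beta
PIGF	PIGF
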