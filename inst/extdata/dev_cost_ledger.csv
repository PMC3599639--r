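item,amount_usd
salaries,152323
fringe,39909
participant_payments,6584
participants_lost_wages,741.50
supplies_equipment_computers,4646.50
software,500
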